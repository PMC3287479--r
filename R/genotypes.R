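#' Genotype matrices
#'
#' Genotypes are stored as an N x M integer matrix of allele1 dosages
#' (0/1/2, NA = missing) plus a variant map (snp_id, chr, 1-based position,
#' allele1, allele2). By convention allele1 is the minor allele as observed
#' in the data (ties broken toward the alphabetically first allele).
#' Variants are kept sorted by (chr, position).
#'
#' @param map data.frame with columns snp_id, chr, pos, allele1, allele2.
#' @param geno integer matrix, individuals x variants, dosage of allele1.
#' @param ids character vector of sample ids.
#' @export
genotype_matrix <- function(map, geno, ids) {
  stopifnot(is.matrix(geno))
  if (nrow(map) != ncol(geno)) stop2("map rows must equal genotype columns")
  if (length(ids) != nrow(geno)) stop2("ids must match genotype rows")
  if (any(map$allele1 == map$allele2)) {
    stop2("allele1 == allele2 for variant ",
          map$snp_id[which(map$allele1 == map$allele2)[1L]])
  }
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop2("genotype codes must be 0/1/2/NA")
  ord <- order(map$chr, map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  geno <- geno[, ord, drop = FALSE]
  colnames(geno) <- map$snp_id
  structure(list(map = map, geno = geno, ids = as.character(ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants\n",
              nrow(x$geno), ncol(x$geno)))
  invisible(x)
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' The .map file has 4 columns (chr, snp_id, cM, pos) or 3 (no cM). Each
#' .ped row is FID IID PAT MAT SEX PHENO followed by two allele tokens per
#' variant; "0" marks a missing allele (both tokens "0" = missing
#' genotype). Allele1 is set to the minor allele counted over all samples.
#'
#' @param ped,map paths to the .ped and .map files.
#' @return a [genotype_matrix()].
#' @export
read_ped_map <- function(ped, map) {
  mp <- utils::read.table(map, colClasses = "character")
  if (ncol(mp) == 3L) mp <- cbind(mp[1:2], cM = "0", mp[3L])
  if (ncol(mp) != 4L) stop2(".map must have 3 or 4 columns")
  names(mp) <- c("chr", "snp_id", "cM", "pos")
  m <- nrow(mp)
  lines <- readLines(ped)
  tok <- strsplit(trimws(lines), "[ \t]+")
  n <- length(tok)
  expected <- 6L + 2L * m
  for (i in seq_len(n)) {
    if (length(tok[[i]]) != expected) {
      stop2(sprintf(".ped line %d has %d fields, expected %d", i,
                    length(tok[[i]]), expected))
    }
  }
  ids <- vapply(tok, `[`, "", 2L)
  a_mat <- matrix("", n, 2L * m)
  for (i in seq_len(n)) a_mat[i, ] <- tok[[i]][-(1:6)]
  geno <- matrix(NA_integer_, n, m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    x <- a_mat[, 2L * j - 1L]
    y <- a_mat[, 2L * j]
    miss <- x == "0" | y == "0"
    alle <- sort(unique(c(x[!miss], y[!miss])))
    if (length(alle) > 2L) {
      stop2("variant ", mp$snp_id[j], " has more than 2 alleles: ",
            paste(alle, collapse = "/"))
    }
    if (length(alle) == 0L) alle <- c("0", "0")  # fully missing variant
    if (length(alle) == 1L) alle <- c(alle, ".")
    cnt1 <- sum(x[!miss] == alle[1L]) + sum(y[!miss] == alle[1L])
    cnt2 <- sum(x[!miss] == alle[2L]) + sum(y[!miss] == alle[2L])
    # allele1 = minor; tie -> alphabetically first (alle is sorted)
    if (cnt2 < cnt1) alle <- alle[2:1]
    a1[j] <- alle[1L]; a2[j] <- alle[2L]
    d <- (x == alle[1L]) + (y == alle[1L])
    d[miss] <- NA_integer_
    geno[, j] <- as.integer(d)
  }
  genotype_matrix(
    data.frame(snp_id = mp$snp_id, chr = as.integer(mp$chr),
               pos = as.integer(mp$pos), allele1 = a1, allele2 = a2,
               stringsAsFactors = FALSE),
    geno, ids)
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' @param gm a [genotype_matrix()].
#' @param ped,map output paths.
#' @export
write_ped_map <- function(gm, ped, map) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mp <- gm$map
  utils::write.table(
    data.frame(mp$chr, mp$snp_id, 0L, mp$pos), map,
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  n <- nrow(gm$geno); m <- ncol(gm$geno)
  out <- character(n)
  pair <- function(d, a1, a2) {
    res <- rep("0 0", length(d))
    res[!is.na(d) & d == 2L] <- paste(a1, a1)
    res[!is.na(d) & d == 1L] <- paste(a1, a2)
    res[!is.na(d) & d == 0L] <- paste(a2, a2)
    res
  }
  cols <- vapply(seq_len(m), function(j)
    pair(gm$geno[, j], mp$allele1[j], mp$allele2[j]), character(n))
  if (n == 1L) cols <- matrix(cols, nrow = 1L)
  body <- apply(cols, 1L, paste, collapse = " ")
  lines <- sprintf("%s %s 0 0 0 -9 %s", gm$ids, gm$ids, body)
  writeLines(lines, ped)
  invisible(ped)
}
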