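#' Read genotypes from PLINK files
#'
#' Reads either the text pair `.ped`/`.map` or the binary trio
#' `.bed`/`.bim`/`.fam` (SNP-major bed only). In both cases calls are stored
#' as counts of the major allele. For `.ped` input the major allele of each
#' SNP is the more frequent allele in the file (ties: alphabetical); for
#' `.bim` input A2 is taken as major, matching PLINK's usual orientation.
#'
#' @param prefix path prefix (without extension). If both formats are
#'   present the binary trio wins.
#' @return A [geno_matrix()].
#' @export
read_plink <- function(prefix) {
  if (file.exists(paste0(prefix, ".bed"))) {
    read_plink_bed(prefix)
  } else if (file.exists(paste0(prefix, ".ped"))) {
    read_plink_ped(prefix)
  } else {
    abort(paste0("no PLINK files found at prefix '", prefix, "'"))
  }
}

#' @rdname read_plink
#' @export
read_plink_ped <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  if (!file.exists(map_path) || !file.exists(ped_path)) {
    abort(paste0("missing .ped/.map at prefix '", prefix, "'"))
  }
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chr", "snp", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m) {
    abort(sprintf(".ped has %d columns; expected %d for %d SNPs",
                  ncol(ped), 6 + 2 * m, m))
  }
  samples <- ped[[2]]
  calls <- matrix(NA_integer_, nrow(ped), m)
  major <- minor <- character(m)
  for (j in seq_len(m)) {
    a1 <- ped[[6 + 2 * j - 1]]
    a2 <- ped[[6 + 2 * j]]
    alle <- c(a1, a2)
    obs <- alle[alle != "0"]
    tab <- sort(table(obs), decreasing = TRUE)
    if (length(tab) > 2) abort(sprintf("SNP '%s' is multi-allelic", map$snp[j]))
    lv <- names(tab)
    if (length(tab) == 2 && tab[1] == tab[2]) lv <- sort(lv)
    major[j] <- if (length(lv) >= 1) lv[1] else "0"
    minor[j] <- if (length(lv) >= 2) lv[2] else "0"
    miss <- a1 == "0" | a2 == "0"
    calls[, j] <- (a1 == major[j]) + (a2 == major[j])
    calls[miss, j] <- NA_integer_
  }
  geno_matrix(calls,
              tibble::tibble(chr = map$chr, snp = map$snp, pos = map$pos,
                             major = major, minor = minor),
              samples)
}

#' @rdname read_plink
#' @export
read_plink_bed <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           col.names = c("chr", "snp", "cm", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("not a PLINK .bed file (bad magic bytes)")
  }
  if (raw[3] != as.raw(0x01)) abort("only SNP-major .bed files are supported")
  bpf <- ceiling(n / 4)                     # bytes per SNP
  if (length(raw) != 3 + bpf * m) abort(".bed size does not match .bim/.fam")
  body <- as.integer(raw[-(1:3)])
  # 2-bit genotype codes per individual: 0 = hom A1, 1 = missing,
  # 2 = het, 3 = hom A2; calls count the major allele (= A2)
  decode <- c(`0` = 0L, `1` = NA_integer_, `2` = 1L, `3` = 2L)
  calls <- matrix(NA_integer_, n, m)
  shifts <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    bytes <- body[(j - 1) * bpf + seq_len(bpf)]
    codes <- integer(bpf * 4)
    for (s in 1:4) {
      codes[seq(s, by = 4, length.out = bpf)] <- (bytes %/% shifts[s]) %% 4L
    }
    calls[, j] <- decode[as.character(codes[seq_len(n)])]
  }
  geno_matrix(calls,
              tibble::tibble(chr = bim$chr, snp = bim$snp, pos = bim$pos,
                             major = bim$a2, minor = bim$a1),
              fam[[2]])
}

#' Write genotypes as PLINK .ped/.map text files
#'
#' @param genotypes a [geno_matrix()].
#' @param prefix output path prefix.
#' @param sex optional named vector (0/1 by sample id) written to the .ped
#'   sex column as 2/1 (PLINK convention); defaults to unknown (0).
#' @return `prefix`, invisibly.
#' @export
write_plink_ped <- function(genotypes, prefix, sex = NULL) {
  snps <- genotypes$snps
  utils::write.table(
    data.frame(snps$chr, snps$snp, 0, snps$pos),
    paste0(prefix, ".map"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  calls <- genotypes$calls
  n <- nrow(calls)
  sex_code <- rep(0L, n)
  if (!is.null(sex)) {
    sx <- sex[genotypes$samples]
    sex_code <- ifelse(is.na(sx), 0L, ifelse(sx == 1, 1L, 2L))
  }
  allele_cols <- vector("list", 2 * ncol(calls))
  for (j in seq_len(ncol(calls))) {
    cj <- calls[, j]
    a1 <- ifelse(is.na(cj), "0", ifelse(cj >= 1, snps$major[j], snps$minor[j]))
    a2 <- ifelse(is.na(cj), "0", ifelse(cj == 2, snps$major[j], snps$minor[j]))
    allele_cols[[2 * j - 1]] <- a1
    allele_cols[[2 * j]] <- a2
  }
  ped <- data.frame(fid = genotypes$samples, iid = genotypes$samples,
                    pat = 0, mat = 0, sex = sex_code, pheno = -9,
                    allele_cols)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}
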