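#' Write genotypes as VCF v4.2
#'
#' Emits one biallelic record per site (`REF=A`, `ALT=G` placeholders,
#' arbitrary positions), missing calls as `./.`, and the per-site mean
#' depth in the INFO field under the key `DPM`.
#'
#' @param g a [geno_matrix()].
#' @param path output path (plain text).
#' @return invisibly, `path`.
#' @export
write_geno_vcf <- function(g, path) {
  n <- nrow(g$geno)
  m <- ncol(g$geno)
  ids <- rownames(g$geno) %||% sprintf("ind%03d", seq_len(n))
  gt <- matrix("./.", n, m)
  gt[!is.na(g$geno) & g$geno == 0] <- "0/0"
  gt[!is.na(g$geno) & g$geno == 1] <- "0/1"
  gt[!is.na(g$geno) & g$geno == 2] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DPM,Number=1,Type=Float,Description=\"Mean depth of coverage across individuals\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- vapply(seq_len(m), function(j) {
    paste(c("1", j * 100L, colnames(g$geno)[j] %||% paste0("snp", j),
            "A", "G", ".", "PASS", sprintf("DPM=%.3f", g$depth[j]), "GT",
            gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses a biallelic VCF (via vcfR), recodes genotypes to 0/1/2 dosage
#' with `NA` for `./.`, and recovers the per-site mean depth from the
#' `DPM` INFO key (falling back to `NA` when absent).
#'
#' @param path VCF path.
#' @param popmap data.frame with columns `id` and `pop` (and optionally
#'   `species`) assigning each sample; defaults to one population.
#' @return A [geno_matrix()].
#' @export
read_geno_vcf <- function(path, popmap = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  code[clean %in% c("0/0")] <- 0L
  code[clean %in% c("0/1", "1/0")] <- 1L
  code[clean %in% c("1/1")] <- 2L
  geno <- t(code)  # individuals x sites
  info <- vcfR::extract.info(v, element = "DPM", as.numeric = TRUE)
  depth <- if (all(is.na(info))) rep(NA_real_, ncol(geno)) else info
  ids <- rownames(geno)
  if (is.null(popmap)) {
    pop <- factor(rep("P1", length(ids)))
    species <- pop
  } else {
    m <- match(ids, popmap$id)
    if (anyNA(m)) stop_tf("popmap missing ids: %s",
                          paste(ids[is.na(m)], collapse = ", "))
    pop <- factor(popmap$pop[m])
    species <- factor((popmap$species %||% popmap$pop)[m])
  }
  geno_matrix(geno, depth = depth, pop = pop, species = species)
}

#' Read and write the plain 0/1/2 matrix alternative
#'
#' CSV with individuals in rows (first column `id`), sites in columns, and
#' a companion CSV for per-site depth.
#'
#' @param g a [geno_matrix()].
#' @param path matrix CSV path; depth is written next to it as
#'   `<path>.depth.csv`.
#' @return `write_geno_matrix` invisibly returns `path`;
#'   `read_geno_matrix` returns a [geno_matrix()].
#' @export
write_geno_matrix <- function(g, path) {
  df <- data.frame(id = rownames(g$geno), pop = as.character(g$pop),
                   species = as.character(g$species), g$geno,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  write.csv(data.frame(site = colnames(g$geno), mean_depth = g$depth),
            paste0(path, ".depth.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_geno_matrix
#' @export
read_geno_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  depth <- read.csv(paste0(path, ".depth.csv"))
  geno <- as.matrix(df[, -(1:3)])
  storage.mode(geno) <- "integer"
  rownames(geno) <- df$id
  geno_matrix(geno, depth = depth$mean_depth, pop = factor(df$pop),
              species = factor(df$species))
}
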