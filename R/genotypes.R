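#' Marker genotype sets
#'
#' Biallelic marker genotypes are stored as a `marker_set`: an integer
#' matrix of minor-allele dosages (rows = individuals, named; columns =
#' markers, named; entries 0/1/2 or `NA`) plus a marker table with columns
#' `marker`, `chrom`, `pos` (1-based bp) and, once estimated, `maf`.
#'
#' @param geno integer dosage matrix, individuals x markers, with dimnames.
#' @param info data.frame with columns `marker`, `chrom`, `pos` and
#'   optionally `maf`; one row per column of `geno`, same order.
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(geno, info) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(!is.null(rownames(geno)), !is.null(colnames(geno)),
            all(c("marker", "chrom", "pos") %in% names(info)),
            nrow(info) == ncol(geno),
            all(info$marker == colnames(geno)))
  if (any(info$pos < 1, na.rm = TRUE)) stop("marker positions must be >= 1")
  rng <- range(geno, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must be 0, 1, 2 or NA")
  info$chrom <- as.character(info$chrom)
  info$pos <- as.integer(info$pos)
  structure(list(geno = geno, info = info), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set: ", nrow(x$geno), " individuals x ", ncol(x$geno),
      " markers\n", sep = "")
  invisible(x)
}

#' Read genotypes from a marker-matrix + map file pair
#'
#' The matrix file is whitespace-delimited with a header row of marker names
#' and a first column of individual IDs; entries are minor-allele dosages
#' 0/1/2 with `NA` (or `-9`) for missing.  The map file has 4 columns:
#' marker, chromosome, bp position, minor allele.
#'
#' @param matrix_path,map_path file paths.
#' @return A [marker_set].
#' @export
read_marker_matrix <- function(matrix_path, map_path) {
  g <- utils::read.table(matrix_path, header = TRUE, check.names = FALSE,
                         row.names = 1L)
  g <- as.matrix(g)
  g[g == -9] <- NA
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("marker", "chrom", "pos", "minor"),
                           stringsAsFactors = FALSE)
  if (!setequal(map$marker, colnames(g)))
    stop("map and matrix marker names disagree")
  map <- map[match(colnames(g), map$marker), , drop = FALSE]
  marker_set(g, data.frame(marker = map$marker, chrom = map$chrom,
                           pos = map$pos, stringsAsFactors = FALSE))
}

#' Write a marker_set to a matrix + map file pair
#' @param ms a [marker_set].
#' @param matrix_path,map_path output paths.
#' @export
write_marker_matrix <- function(ms, matrix_path, map_path) {
  utils::write.table(data.frame(id = rownames(ms$geno), ms$geno,
                                check.names = FALSE),
                     matrix_path, quote = FALSE, row.names = FALSE, sep = "\t")
  utils::write.table(data.frame(ms$info$marker, ms$info$chrom, ms$info$pos,
                                "A"),
                     map_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(matrix_path)
}

#' Read biallelic genotypes from a VCF file
#'
#' Uses the GT field of a VCF; multiallelic records are skipped (with a
#' warning) or split is not attempted.  Missing genotypes (`./.`) become
#' `NA`.  Dosage counts the ALT allele; alleles are relabelled to the minor
#' allele at frequency-estimation time, not here.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param multiallelic `"skip"` (default) drops records with >1 ALT allele.
#' @return A [marker_set].
#' @export
read_vcf_genotypes <- function(path, multiallelic = c("skip")) {
  multiallelic <- match.arg(multiallelic)
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  geno <- t(dos)
  colnames(geno) <- ids
  marker_set(geno, data.frame(marker = ids, chrom = fix[, "CHROM"],
                              pos = as.integer(fix[, "POS"]),
                              stringsAsFactors = FALSE))
}

#' Estimate the minor allele frequency of a marker
#'
#' Counts alleles either among pedigree founders only (the natural reference
#' population for pedigree data) or among all genotyped individuals.  If the
#' counted allele has frequency above 0.5 the alleles are relabelled and the
#' returned frequency is `1 - p` (attribute `relabelled`).
#'
#' @param dosage named integer vector of dosages (0/1/2/NA).
#' @param peds list of [Pedigree] objects (needed for `founders_only`).
#' @param method `"founders_only"` (default) or `"all_counted"`.
#' @return Minor allele frequency in `[0, 0.5]`, with attributes
#'   `relabelled` (logical) and `n_alleles` (alleles counted).
#' @export
estimate_allele_freq <- function(dosage, peds = NULL,
                                 method = c("founders_only", "all_counted")) {
  method <- match.arg(method)
  if (method == "founders_only") {
    if (is.null(peds)) stop("founders_only estimation needs `peds`")
    fnd <- unlist(lapply(peds, ped_founders), use.names = FALSE)
    dosage <- dosage[names(dosage) %in% fnd]
  }
  dosage <- dosage[!is.na(dosage)]
  if (!length(dosage))
    stop("allele frequency estimation failed: all genotypes missing in the ",
         "reference set")
  p <- sum(dosage) / (2 * length(dosage))
  relab <- p > 0.5
  maf <- if (relab) 1 - p else p
  structure(maf, relabelled = relab, n_alleles = 2L * length(dosage))
}

#' Attach estimated minor allele frequencies to a marker set
#'
#' @inheritParams estimate_allele_freq
#' @param ms a [marker_set].
#' @return The marker set with an updated `maf` column; markers whose
#'   counted allele exceeded frequency 0.5 have their dosages flipped to
#'   count the minor allele.
#' @export
set_maf <- function(ms, peds = NULL,
                    method = c("founders_only", "all_counted")) {
  method <- match.arg(method)
  maf <- numeric(ncol(ms$geno))
  for (k in seq_len(ncol(ms$geno))) {
    f <- estimate_allele_freq(ms$geno[, k], peds, method)
    if (attr(f, "relabelled")) ms$geno[, k] <- 2L - ms$geno[, k]
    maf[k] <- as.numeric(f)
  }
  ms$info$maf <- maf
  ms
}

#' Classify minor allele frequency into rare / low-frequency / common
#'
#' Cut-points follow the convention: rare below 1\%, low-frequency in
#' `[1\%, 5\%)`, common at or above 5\%; the three classes partition
#' `[0, 0.5]` exactly.
#'
#' @param maf numeric vector in `[0, 0.5]`.
#' @return factor with levels `rare`, `low`, `common`.
#' @export
classify_maf <- function(maf) {
  if (any(is.na(maf)) || any(maf < 0 | maf > 0.5))
    stop("maf values must lie in [0, 0.5]")
  cls <- ifelse(maf < 0.01, "rare", ifelse(maf < 0.05, "low", "common"))
  factor(cls, levels = c("rare", "low", "common"))
}

#' Sample markers for a two-point linkage scan
#'
#' Uniform sampling without replacement among markers passing a minor allele
#' frequency filter (boundary inclusive), excluding any previously sampled
#' markers; reproducible under a seed.
#'
#' @param ms a [marker_set] with `maf` set (see [set_maf]).
#' @param n number of markers to draw.
#' @param maf_min inclusive MAF filter (default 0.05).
#' @param exclude character vector of marker names to exclude.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return Character vector of sampled marker names, in map order.
#' @export
sample_markers <- function(ms, n, maf_min = 0.05, exclude = character(),
                           seed = NULL) {
  if (is.null(ms$info$maf)) stop("marker set has no maf; run set_maf() first")
  eligible <- ms$info$marker[ms$info$maf >= maf_min &
                               !ms$info$marker %in% exclude]
  if (n > length(eligible))
    stop("requested ", n, " markers but only ", length(eligible),
         " are eligible after MAF >= ", maf_min, " and exclusions")
  picked <- with_seed(seed, sample(eligible, n))
  ms$info$marker[ms$info$marker %in% picked]
}

#' Subset a marker_set by marker names or individuals
#' @param ms a [marker_set].
#' @param markers,ids optional character vectors.
#' @return The subsetted [marker_set].
#' @export
subset_markers <- function(ms, markers = NULL, ids = NULL) {
  if (!is.null(markers)) {
    keep <- ms$info$marker %in% markers
    ms$geno <- ms$geno[, keep, drop = FALSE]
    ms$info <- ms$info[keep, , drop = FALSE]
  }
  if (!is.null(ids)) ms$geno <- ms$geno[rownames(ms$geno) %in% ids, ,
                                        drop = FALSE]
  ms
}
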