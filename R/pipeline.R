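#' Pipeline configuration
#'
#' Configuration for [run_multiphase].  Inputs may be given in-memory
#' (`peds`, `records`, `gwas`, `seq`) or as file paths (`ped_file`,
#' `pheno_file`, `gwas_matrix`/`gwas_map`, `seq_matrix`/`seq_map`);
#' in-memory objects take precedence.
#'
#' @param peds list of [Pedigree] objects (or `ped_file`).
#' @param records exam record data.frame (or `pheno_file`, a CSV with
#'   columns id, exam, sbp, age, sex, smoke, med and optionally fam).
#' @param gwas [marker_set] of common scan markers (or
#'   `gwas_matrix`/`gwas_map` paths).
#' @param seq_ms [marker_set] of dense regional variants (or
#'   `seq_matrix`/`seq_map`); defaults to `gwas` when absent.
#' @param ped_file,pheno_file,gwas_matrix,gwas_map,seq_matrix,seq_map file
#'   paths used when the in-memory objects are `NULL`.
#' @param out_dir output directory.
#' @param n_markers numbers of markers to sample for the linkage scan; a
#'   vector performs repeated samplings with previous samples excluded and
#'   takes the union of selected regions forward.
#' @param maf_min MAF filter for sampled markers (inclusive, default 0.05).
#' @param lod_threshold region selection threshold (default 1.2).
#' @param merge_bp region merge distance (default 10 Mb).
#' @param region_override optional manual region `"chr:start-end"` in bp
#'   (e.g. `"3:165000000-175000000"`) used instead of the selected regions.
#' @param linkage_vc include the marker-specific linkage variance component
#'   in association fits.
#' @param mendel_policy `"error"` or `"prior"` (see [compute_ibd]).
#' @param phases character subset of `c("adjust", "linkage", "associate")`.
#' @param state_limit,n_ibd_samples IBD engine settings.
#' @param seed base seed; every random draw derives from it by fixed
#'   phase-keyed offsets.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(peds = NULL, records = NULL, gwas = NULL,
                            seq_ms = NULL, ped_file = NULL,
                            pheno_file = NULL, gwas_matrix = NULL,
                            gwas_map = NULL, seq_matrix = NULL,
                            seq_map = NULL, out_dir = tempfile("famscan"),
                            n_markers = 100, maf_min = 0.05,
                            lod_threshold = 1.2, merge_bp = 1e7,
                            region_override = NULL, linkage_vc = FALSE,
                            mendel_policy = "prior",
                            phases = c("adjust", "linkage", "associate"),
                            state_limit = 2^22, n_ibd_samples = 10000,
                            seed = 1L) {
  stopifnot(lod_threshold > 0, merge_bp > 0)
  if (!is.null(region_override)) parse_region(region_override)
  structure(as.list(environment()), class = "pipeline_config")
}

parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4) stop("region must be 'chr:start-end' in bp: ", x)
  start <- as.numeric(m[3]); end <- as.numeric(m[4])
  if (start > end) stop("region bounds out of order: ", x)
  data.frame(chrom = m[2], start_bp = start, end_bp = end,
             peak_marker = NA_character_, peak_lod = NA_real_,
             n_markers = NA_integer_, stringsAsFactors = FALSE)
}

# merge overlapping/adjacent region intervals (closed, 1-based)
merge_regions <- function(reg) {
  if (!nrow(reg)) return(reg)
  out <- list()
  for (ch in unique(reg$chrom)) {
    sub <- reg[reg$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start_bp), , drop = FALSE]
    cur <- sub[1, , drop = FALSE]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start_bp[i] <= cur$end_bp) {
        cur$end_bp <- max(cur$end_bp, sub$end_bp[i])
        if (!is.na(sub$peak_lod[i]) &&
            (is.na(cur$peak_lod) || sub$peak_lod[i] > cur$peak_lod)) {
          cur$peak_lod <- sub$peak_lod[i]
          cur$peak_marker <- sub$peak_marker[i]
        }
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- sub[i, , drop = FALSE]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, out)
}

#' Run the multiphase linkage and association workflow
#'
#' Executes, per the configured phases: (1) censoring-aware phenotype
#' adjustment per exam and construction of the adjusted phenotype `R`; (2)
#' a two-point variance-components linkage scan over randomly sampled
#' common markers, with LOD-based region selection; (3) MG and QTDT
#' association of every variant whose position lies inside a selected (or
#' overridden) region, the interval being closed and 1-based.  Per-phase
#' tables are written to `cfg$out_dir` as TSV/CSV together with a JSON
#' manifest recording the package version, seeds and counts.  Per-marker
#' soft failures are tallied in the manifest, not fatal; a phase's hard
#' error aborts with the phase named.
#'
#' @param cfg a [pipeline_config].
#' @return A report list: `adjusted`, `fits`, `linkage`, `regions`,
#'   `association`, `manifest` (also written as files).
#' @export
run_multiphase <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  peds <- cfg$peds %||% read_pedigree(cfg$ped_file)
  records <- cfg$records %||%
    utils::read.table(cfg$pheno_file, header = TRUE, sep = ",",
                      stringsAsFactors = FALSE)
  gwas <- cfg$gwas %||% (if (!is.null(cfg$gwas_matrix))
    read_marker_matrix(cfg$gwas_matrix, cfg$gwas_map))
  seqms <- cfg$seq_ms %||% (if (!is.null(cfg$seq_matrix))
    read_marker_matrix(cfg$seq_matrix, cfg$seq_map)) %||% gwas
  if (!"fam" %in% names(records)) {
    fmap <- ped_fam_map(peds)
    records$fam <- unname(fmap[as.character(records$id)])
  }
  kin <- kinship_list(peds)
  manifest <- list(package = "famscan",
                   version = as.character(utils::packageVersion("famscan")),
                   seed = cfg$seed, phases = cfg$phases,
                   n_pedigrees = length(peds),
                   soft_failures = list())
  report <- list()

  ## phase 1: phenotype adjustment -------------------------------------
  Rtab <- phase_try("adjust", {
    exams <- sort(unique(records$exam[records$exam %in% 1:3]))
    fits <- lapply(exams, function(e)
      fit_censored_exam(records[records$exam == e, , drop = FALSE]))
    names(fits) <- as.character(exams)
    adj <- build_adjusted_phenotype(fits, records)
    write_adjusted_phenotype(adj, file.path(cfg$out_dir, "adjusted_R.csv"))
    write_fit_report(fits, file.path(cfg$out_dir, "phenotype_fits.json"))
    report$fits <- fits
    adj
  })
  report$adjusted <- Rtab
  manifest$n_phenotyped <- nrow(Rtab)
  manifest$n_skipped_phenotype <- length(attr(Rtab, "skipped"))

  ## phase 2: two-point linkage scan ------------------------------------
  regions <- NULL
  if ("linkage" %in% cfg$phases) {
    lk <- phase_try("linkage", {
      gw <- set_maf(gwas, peds)
      null <- fit_polygenic_null(Rtab, peds, kin)
      sampled <- character(0)
      scans <- list()
      regs <- list()
      for (k in seq_along(cfg$n_markers)) {
        mk <- sample_markers(gw, cfg$n_markers[k], cfg$maf_min,
                             exclude = sampled,
                             seed = cfg$seed + 1000L + k)
        sampled <- c(sampled, mk)
        sc <- linkage_scan(Rtab, peds, kin, gw, markers = mk, null = null,
                           state_limit = cfg$state_limit,
                           n_samples = cfg$n_ibd_samples,
                           seed = cfg$seed + 2000L + 100000L * k,
                           mendel_policy = cfg$mendel_policy)
        sc$snp_set <- k
        scans[[k]] <- sc
        regs[[k]] <- select_regions(sc, cfg$lod_threshold, cfg$merge_bp)
      }
      list(null = null, scan = do.call(rbind, scans),
           regions = merge_regions(do.call(rbind, regs)))
    })
    regions <- lk$regions
    utils::write.table(lk$scan, file.path(cfg$out_dir, "linkage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(regions, file.path(cfg$out_dir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$polygenic_null <- lk$null
    report$linkage <- lk$scan
    manifest$n_markers_scanned <- nrow(lk$scan)
    manifest$max_lod <- if (nrow(lk$scan)) max(lk$scan$lod) else NA_real_
    manifest$n_regions <- nrow(regions)
  }

  ## phase 3: regional association --------------------------------------
  if ("associate" %in% cfg$phases) {
    if (!is.null(cfg$region_override))
      regions <- parse_region(cfg$region_override)
    if (is.null(regions) || !nrow(regions)) {
      manifest$association <- paste("skipped: no region exceeded LOD",
                                    cfg$lod_threshold,
                                    "and no region_override was given")
    } else {
      res <- phase_try("associate", {
        sq <- set_maf(seqms, peds)
        inreg <- rep(FALSE, nrow(sq$info))
        for (i in seq_len(nrow(regions)))
          inreg <- inreg | (sq$info$chrom == regions$chrom[i] &
                              sq$info$pos >= regions$start_bp[i] &
                              sq$info$pos <= regions$end_bp[i])
        assoc_scan(Rtab, peds, kin, sq,
                   markers = sq$info$marker[inreg],
                   linkage_vc = cfg$linkage_vc,
                   state_limit = cfg$state_limit,
                   n_samples = cfg$n_ibd_samples,
                   seed = cfg$seed + 3000L,
                   mendel_policy = cfg$mendel_policy)
      })
      utils::write.table(res, file.path(cfg$out_dir, "association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$association <- res
      manifest$n_region_variants <- nrow(res)
      manifest$soft_failures$assoc_mg <- sum(res$flag_mg == "failed")
      manifest$soft_failures$assoc_qtdt <- sum(res$flag_qtdt == "failed")
    }
  }

  report$regions <- regions
  report$manifest <- manifest
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

# evaluate a phase body, converting hard errors into phase-named aborts
phase_try <- function(phase, expr) {
  tryCatch(expr,
           error = function(e)
             stop("pipeline phase '", phase, "' failed: ",
                  conditionMessage(e), call. = FALSE))
}

#' Individual-to-family map for a pedigree list
#' @param peds list of [Pedigree] objects.
#' @return Named character vector mapping individual ID to family ID.
#' @export
ped_fam_map <- function(peds) {
  out <- unlist(lapply(peds, function(p)
    setNames(rep(p$family_id, nrow(p$members)), p$members$id)))
  out
}
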