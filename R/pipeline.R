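#' Run configuration for the scheme-comparison pipeline
#'
#' Bundles every run-level constant: input files, chromosomes, binning
#' resolution, quality threshold, power-law index, weighting schemes and
#' referent, optional balancing, MDS settings and the master seed.
#'
#' @param cluster_files Character vector of SPRITE cluster file paths (their
#'   clusters are pooled, then split by chromosome).
#' @param chromosomes Named numeric vector of chromosome lengths in base
#'   pairs, e.g. `c(chr1 = 248956422)`.
#' @param hic_files Optional named character vector of Hi-C triplet files,
#'   keyed by chromosome (needed by [run_hic_comparison()]).
#' @param resolution Bin width; default 25000.
#' @param mapq_min MAPQ threshold; default 30.
#' @param alpha Power-law index; default `-1/3` (alternative: `-1.08`).
#' @param weight_power Inverse-distance MDS weight exponent; default 1.
#' @param schemes Weighting schemes to run; default all three.
#' @param referent Referent scheme for Procrustes alignment; default
#'   `"N-W"` (the intermediary scheme). Must be in `schemes`.
#' @param normalize Balance each contact matrix before the distance
#'   transform; default `FALSE` (primary analyses are comparative and
#'   unnormalized).
#' @param mds An [mds_config()].
#' @param seed Master seed; per-chromosome MDS seeds are derived from it and
#'   matched across schemes, so RMSE differences reflect weighting, not
#'   initialization noise.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cluster_files, chromosomes, hic_files = NULL,
                       resolution = 25000L, mapq_min = 30L, alpha = -1/3,
                       weight_power = 1,
                       schemes = c("U-W", "N-W", "O-W"), referent = "N-W",
                       normalize = FALSE, mds = mds_config(), seed = 1L) {
  schemes <- match.arg(schemes, c("U-W", "N-W", "O-W"), several.ok = TRUE)
  if (!referent %in% schemes) stop("referent scheme must be one of 'schemes'")
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop("chromosomes must be a named vector of lengths")
  if (alpha >= 0) stop("alpha must be negative")
  structure(
    list(cluster_files = cluster_files, chromosomes = chromosomes,
         hic_files = hic_files, resolution = as.numeric(resolution),
         mapq_min = as.integer(mapq_min), alpha = alpha,
         weight_power = weight_power, schemes = schemes, referent = referent,
         normalize = isTRUE(normalize), mds = mds, seed = as.integer(seed)),
    class = "run_config"
  )
}

# distance + MDS path shared by SPRITE and Hi-C reconstructions
reconstruct_from_contacts <- function(C, cfg, mds_seed) {
  if (cfg$normalize) C <- balance_matrix(C)
  D <- power_law_distance(C, alpha = cfg$alpha, weight_power = cfg$weight_power)
  m <- cfg$mds
  m$seed <- mds_seed
  smacof_mds(D, m)
}

#' Run the full weighting-scheme comparison
#'
#' For every configured chromosome: bin the clusters, build one contact
#' matrix per weighting scheme (optionally balanced), transform to
#' dissimilarities, reconstruct by weighted SMACOF with matched
#' initialization across schemes, and align each reconstruction onto the
#' referent scheme's by reflection-similarity Procrustes. Pooled span
#' quantile thresholds are computed before per-chromosome features, and
#' per-chromosome RMSEs are regressed on each feature (unadjusted and
#' chromosome-length-adjusted). A per-chromosome failure (e.g. a
#' disconnected contact graph) skips that chromosome with a recorded reason
#' and never aborts the run.
#'
#' @param cfg A [run_config()].
#' @param clusters Optional pre-read list of `sprite_cluster` objects; when
#'   `NULL` (default), `cfg$cluster_files` are read.
#' @return An object of class `run_report`: list with
#'   \describe{
#'     \item{rmse}{data frame: chromosome, scheme, rmse vs referent
#'       (referent row included as a zero self-check), MDS stress.}
#'     \item{features}{data frame of per-chromosome features.}
#'     \item{regressions}{data frame: scheme, feature, adjusted, slope, p,
#'       and the length-covariate slope/p when adjusted.}
#'     \item{degree_distance}{a [degree_distance_table()].}
#'     \item{thresholds}{pooled quintile/decile span thresholds (bp).}
#'     \item{skipped}{data frame of skipped chromosomes and reasons.}
#'     \item{reconstructions}{per-chromosome list of per-scheme
#'       `reconstruction` objects (referent included).}
#'     \item{config}{the `run_config` (provenance).}
#'   }
#' @export
run_comparison <- function(cfg, clusters = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(clusters)) {
    clusters <- unlist(lapply(cfg$cluster_files, read_sprite_clusters,
                              mapq_min = cfg$mapq_min,
                              chromosome_filter = names(cfg$chromosomes)),
                       recursive = FALSE)
  }
  chroms <- names(cfg$chromosomes)
  binnings <- stats::setNames(lapply(chroms, function(ch)
    genome_binning(ch, cfg$chromosomes[[ch]], cfg$resolution)), chroms)

  binned <- stats::setNames(lapply(chroms, function(ch)
    bin_clusters(clusters, binnings[[ch]])), chroms)

  # pooled thresholds first, so "long-distance" means the same span everywhere
  all_spans <- unlist(lapply(chroms, function(ch)
    vapply(binned[[ch]], cluster_span, 0, binning = binnings[[ch]])))
  if (length(all_spans) == 0L) stop("no qualifying clusters on any chromosome")
  thr <- c(quintile = unname(pooled_quantile_thresholds(all_spans, 0.8)),
           decile = unname(pooled_quantile_thresholds(all_spans, 0.9)))

  rmse_rows <- list()
  feat_rows <- list()
  skipped <- list()
  recon_out <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[[ci]]
    res <- tryCatch({
      cls <- binned[[ch]]
      if (length(cls) == 0L) stop("no qualifying clusters")
      mds_seed <- derive_seed(cfg$seed, 100L + ci)
      recons <- lapply(cfg$schemes, function(sc) {
        C <- build_contact_matrix(cls, sc, binnings[[ch]])
        reconstruct_from_contacts(C, cfg, mds_seed)
      })
      names(recons) <- cfg$schemes
      ref <- recons[[cfg$referent]]
      rows <- lapply(cfg$schemes, function(sc) {
        pr <- procrustes_align(ref, recons[[sc]])
        data.frame(chromosome = ch, scheme = sc, rmse = pr$rmse,
                   stress = recons[[sc]]$stress,
                   stringsAsFactors = FALSE)
      })
      list(df = do.call(rbind, rows), recons = recons)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(chromosome = ch, reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
      next
    }
    rmse_rows[[length(rmse_rows) + 1L]] <- res$df
    recon_out[[ch]] <- res$recons
    f <- chromosome_features(binned[[ch]], thr, binnings[[ch]])
    feat_rows[[length(feat_rows) + 1L]] <- as.data.frame(unclass(f))
  }
  rmse_df <- if (length(rmse_rows)) do.call(rbind, rmse_rows) else
    data.frame(chromosome = character(), scheme = character(),
               rmse = numeric(), stress = numeric())
  feat_df <- if (length(feat_rows)) do.call(rbind, feat_rows) else NULL
  skipped_df <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(chromosome = character(), reason = character())

  reg_df <- run_feature_regressions(rmse_df, feat_df, cfg)

  ddt <- degree_distance_table(unlist(binned, recursive = FALSE), binnings)

  structure(
    list(rmse = rmse_df, features = feat_df, regressions = reg_df,
         degree_distance = ddt, thresholds = thr, skipped = skipped_df,
         reconstructions = recon_out, config = cfg),
    class = "run_report"
  )
}

# RMSE-vs-feature regressions for each non-referent scheme, both unadjusted
# and chromosome-length-adjusted; chromosomes with no clusters never reach
# here (they are skipped upstream).
run_feature_regressions <- function(rmse_df, feat_df, cfg) {
  out <- list()
  feats <- c("pct_many_gt3", "pct_many_gt10", "pct_long", "pct_long_decile",
             "length_bp")
  for (sc in setdiff(cfg$schemes, cfg$referent)) {
    sub <- rmse_df[rmse_df$scheme == sc, , drop = FALSE]
    if (is.null(feat_df)) next
    m <- merge(sub, feat_df, by = "chromosome")
    for (fe in feats) {
      for (adj in if (fe == "length_bp") FALSE else c(FALSE, TRUE)) {
        res <- tryCatch(
          regress_rmse(m$rmse, m[[fe]], length_bp = m$length_bp,
                       adjust_length = adj),
          error = function(e) NULL)
        if (is.null(res)) next
        out[[length(out) + 1L]] <- data.frame(
          scheme = sc, feature = fe, adjusted_for_length = adj,
          slope = unname(res$slopes["x"]), p = unname(res$p_values["x"]),
          slope_length = if (adj) unname(res$slopes["length_bp"]) else NA_real_,
          p_length = if (adj) unname(res$p_values["length_bp"]) else NA_real_,
          r_squared = res$r_squared, n = res$n, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(scheme = character(), feature = character(),
               adjusted_for_length = logical(), slope = numeric(),
               p = numeric(), slope_length = numeric(), p_length = numeric(),
               r_squared = numeric(), n = integer())
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  nch <- length(unique(x$rmse$chromosome))
  cat(sprintf("  %d chromosome(s) reconstructed under schemes: %s (referent %s)\n",
              nch, paste(x$config$schemes, collapse = ", "), x$config$referent))
  if (nrow(x$skipped))
    cat("  skipped:", paste(x$skipped$chromosome, collapse = ", "), "\n")
  agg <- stats::aggregate(rmse ~ scheme, data = x$rmse, FUN = mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  mean RMSE vs %s  %-4s %.6g\n", x$config$referent,
                agg$scheme[i], agg$rmse[i]))
  invisible(x)
}

#' Compare SPRITE reconstructions against a Hi-C target
#'
#' Reconstructs each chromosome from its Hi-C contact matrix through the
#' same distance/MDS path, then aligns the per-scheme SPRITE
#' reconstructions onto the Hi-C reconstruction and reports per-chromosome
#' RMSEs and the winning (smallest-RMSE) scheme.
#'
#' @param cfg A [run_config()] with `hic_files` set (or use `hic_matrices`).
#' @param clusters Optional pre-read clusters, as in [run_comparison()].
#' @param hic_matrices Optional named list of [contact_matrix()] objects
#'   keyed by chromosome, overriding `cfg$hic_files` (useful with
#'   [simulate_hic()]).
#' @return A list with `rmse` (data frame: chromosome, scheme, rmse vs
#'   Hi-C), `winners` (named character, per chromosome), `winner_tally`
#'   (table over schemes), `skipped`.
#' @export
run_hic_comparison <- function(cfg, clusters = NULL, hic_matrices = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(hic_matrices) && is.null(cfg$hic_files))
    stop("Hi-C input required: set cfg$hic_files or pass hic_matrices")
  if (is.null(clusters)) {
    clusters <- unlist(lapply(cfg$cluster_files, read_sprite_clusters,
                              mapq_min = cfg$mapq_min,
                              chromosome_filter = names(cfg$chromosomes)),
                       recursive = FALSE)
  }
  chroms <- names(cfg$chromosomes)
  rows <- list()
  winners <- character(0)
  skipped <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[[ci]]
    res <- tryCatch({
      binning <- genome_binning(ch, cfg$chromosomes[[ch]], cfg$resolution)
      Chic <- if (!is.null(hic_matrices)) hic_matrices[[ch]] else
        read_hic_triplets(cfg$hic_files[[ch]], binning)
      if (is.null(Chic)) stop("no Hi-C matrix for ", ch)
      if (nrow(Chic$values) != binning$n_bins)
        stop("Hi-C bin count (", nrow(Chic$values), ") does not match ",
             binning$n_bins, " bins on ", ch)
      cls <- bin_clusters(clusters, binning)
      if (length(cls) == 0L) stop("no qualifying clusters")
      mds_seed <- derive_seed(cfg$seed, 200L + ci)
      target <- reconstruct_from_contacts(Chic, cfg, mds_seed)
      rr <- lapply(cfg$schemes, function(sc) {
        C <- build_contact_matrix(cls, sc, binning)
        rec <- reconstruct_from_contacts(C, cfg, mds_seed)
        data.frame(chromosome = ch, scheme = sc,
                   rmse = procrustes_align(target, rec)$rmse,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(chromosome = ch, reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- res
    winners[[ch]] <- res$scheme[which.min(res$rmse)]
  }
  rmse_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chromosome = character(), scheme = character(), rmse = numeric())
  list(rmse = rmse_df,
       winners = winners,
       winner_tally = table(factor(winners, levels = cfg$schemes)),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(chromosome = character(), reason = character()))
}

#' Write run-report tables as TSV files
#'
#' Emits `rmse.tsv`, `features.tsv`, `regressions.tsv`,
#' `degree_distance.tsv` and `summary.txt` into a directory.
#'
#' @param report A `run_report` from [run_comparison()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$rmse, "rmse.tsv")
  if (!is.null(report$features)) wt(report$features, "features.tsv")
  wt(report$regressions, "regressions.tsv")
  utils::write.table(report$degree_distance$counts,
                     file.path(dir, "degree_distance.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  invisible(dir)
}
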