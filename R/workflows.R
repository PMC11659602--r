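#' Kinetics workflow: plates to covalent parameters
#'
#' Runs the full quench-time analysis for one inhibitor: per-time 4PL
#' IC50 fits on each replicate plate, a per-replicate Krippendorff fit,
#' and a pooled fit on the concatenated usable points of all
#' replicates. Writes `ic50_series.csv` and `fit_report.json` (fields
#' `peptide`, `K_I_uM`, `K_I_se`, `kinact_per_min`, `kinact_se`,
#' `kinact_over_KI_M_min`, `n_points`, `flags`, plus the config hash
#' and seed) to `out_dir`. Weak inhibitors whose curves are all
#' incomplete yield a flagged report with no parameters rather than an
#' error.
#'
#' @param plates an [activity_plate] or list of replicate plates (or
#'   paths to plate CSVs).
#' @param context a [substrate_context].
#' @param out_dir output directory (created); `NULL` skips writing.
#' @param peptide label carried into the report.
#' @param fix_limits passed to [fit_four_pl].
#' @param enzyme_conc_uM passed to [ic50_timecourse].
#' @param seed recorded in the report (the analysis itself is
#'   deterministic).
#' @return list with `series` (per replicate), `fits` (per replicate),
#'   `pooled` (the pooled `covalent_fit` or `NULL`), `report`.
#' @export
run_kinetics_workflow <- function(plates, context = substrate_context(),
                                  out_dir = NULL, peptide = "peptide",
                                  fix_limits = FALSE, enzyme_conc_uM = 0.05,
                                  seed = 1L) {
  if (inherits(plates, "activity_plate")) plates <- list(plates)
  plates <- lapply(plates, function(p)
    if (is.character(p)) read_plate_csv(p) else p)
  stopifnot(all(vapply(plates, inherits, logical(1L), "activity_plate")))
  flags <- character(0)
  series <- list()
  fits <- list()
  for (i in seq_along(plates)) {
    s <- withCallingHandlers(
      ic50_timecourse(plates[[i]], fix_limits = fix_limits,
                      enzyme_conc_uM = enzyme_conc_uM),
      warning = function(w) {
        flags <<- union(flags, "tight_binding")
        invokeRestart("muffleWarning")
      })
    series[[i]] <- s
    fits[[i]] <- if (isTRUE(attr(s, "unfittable"))) NULL else
      tryCatch(fit_krippendorff(s, context), error = function(e) NULL)
  }
  usable_all <- do.call(rbind, lapply(series, function(s) s[s$usable, ]))
  pooled <- NULL
  if (!is.null(usable_all) && nrow(usable_all) >= 2L) {
    pooled <- tryCatch(fit_krippendorff(usable_all, context),
                       error = function(e) NULL)
  }
  if (is.null(pooled)) flags <- union(flags, "incomplete")
  if (!is.null(pooled) && pooled$at_bound) flags <- union(flags, "at_bound")

  config <- list(workflow = "kinetics", peptide = peptide,
                 S_mM = context$S, K_M_mM = context$K_M,
                 fix_limits = fix_limits, enzyme_conc_uM = enzyme_conc_uM,
                 seed = seed)
  report <- list(
    peptide = peptide,
    K_I_uM = if (is.null(pooled)) NULL else pooled$params$K_I,
    K_I_se = if (is.null(pooled)) NULL else unname(pooled$se[["K_I"]]),
    kinact_per_min = if (is.null(pooled)) NULL else pooled$params$k_inact,
    kinact_se = if (is.null(pooled)) NULL else unname(pooled$se[["k_inact"]]),
    kinact_over_KI_M_min = if (is.null(pooled)) NULL else
      kinact_over_KI(pooled$params),
    n_points = if (is.null(usable_all)) 0L else nrow(usable_all),
    n_replicates = length(plates),
    flags = flags, seed = seed, config_hash = .config_hash(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ser_df <- do.call(rbind, lapply(seq_along(series), function(i) {
      s <- series[[i]]
      data.frame(replicate = plates[[i]]$replicate, t_min = s$t,
                 ic50_uM = s$ic50, usable = s$usable)
    }))
    utils::write.csv(ser_df, file.path(out_dir, "ic50_series.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "fit_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  }
  list(series = series, fits = fits, pooled = pooled, report = report)
}

#' Selection workflow: per-round FASTQ to enrichment report
#'
#' Decodes and tabulates every round, computes warhead-free fractions,
#' enrichment trajectories of the top sequences of the final round, and
#' greedy family assignments of the final-round top sequences. Writes
#' per-round ranked-count CSVs, `enrichment.csv`, `families.csv` and
#' `summary.json` to `out_dir`. All outputs are deterministic for
#' identical inputs.
#'
#' @param fastq_per_round FASTQ paths (round order) or list of
#'   in-memory read vectors.
#' @param out_dir output directory; `NULL` skips writing.
#' @param scheme a [code_scheme].
#' @param track_top number of final-round top peptides to track and
#'   cluster.
#' @param max_dist family-clustering distance threshold.
#' @param seed recorded in outputs (the analysis is deterministic).
#' @return list with `counts` (a `round_counts`), `enrichment`,
#'   `families`, `summary`.
#' @export
run_selection_workflow <- function(fastq_per_round, out_dir = NULL,
                                   scheme = code_scheme(), track_top = 20L,
                                   max_dist = 2L, seed = 1L) {
  counts <- tabulate_rounds(fastq_per_round, scheme)
  if (sum(counts$totals) == 0L) stop("zero decodable reads in all rounds")
  R <- length(counts$rounds)
  final <- counts$rounds[[R]]
  top <- utils::head(final$peptide, track_top)
  enr <- enrichment_trajectory(counts, top)
  fam <- cluster_families(top, utils::head(final$count, track_top),
                          max_dist = max_dist)
  wh_frac <- vapply(seq_len(R), function(r)
    if (counts$totals[r] > 0) warhead_missing_fraction(counts, r)
    else NA_real_, numeric(1L))
  config <- list(workflow = "selection", track_top = track_top,
                 max_dist = max_dist, seed = seed)
  summary <- list(
    n_rounds = R,
    reads_total = counts$raw_totals,
    reads_valid = counts$totals,
    warhead_missing_pct = wh_frac,
    n_families_top = length(unique(fam$family)),
    seed = seed, config_hash = .config_hash(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in seq_len(R)) {
      df <- counts$rounds[[r]]
      df$flags <- ""
      utils::write.csv(df, file.path(out_dir,
                                     sprintf("counts_%s.csv",
                                             names(counts$rounds)[r])),
                       row.names = FALSE)
    }
    utils::write.csv(enr, file.path(out_dir, "enrichment.csv"),
                     row.names = FALSE)
    utils::write.csv(fam, file.path(out_dir, "families.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(counts = counts, enrichment = enr, families = fam, summary = summary)
}

#' SPR workflow: sensorgram to covalent constants
#'
#' Fits the two-state covalent model to a sensorgram and derives
#' `K_i`, `k_inact` and their ratio; writes `spr_report.json`.
#'
#' @param gram a `sensorgram` (or a CSV path plus `scheme`).
#' @param scheme required when `gram` is a path.
#' @param out_dir output directory; `NULL` skips writing.
#' @param seed recorded in the report.
#' @return list with `fit` (a `two_state_fit`), `constants`, `report`.
#' @export
run_spr_workflow <- function(gram, scheme = NULL, out_dir = NULL, seed = 1L) {
  if (is.character(gram)) {
    stopifnot(!is.null(scheme))
    gram <- read_sensorgram_csv(gram, scheme)
  }
  fit <- fit_two_state(gram)
  konst <- derive_covalent_constants(fit$params)
  config <- list(workflow = "spr", seed = seed)
  report <- list(
    K_i_uM = konst$K_i_uM, kinact_per_min = konst$k_inact_per_min,
    kinact_over_Ki_M_min = konst$ratio_M_min,
    k_plus1 = fit$params$k_plus1, k_minus1 = fit$params$k_minus1,
    k_plus2 = fit$params$k_plus2, Rmax = fit$params$Rmax,
    se = as.list(fit$se), rss = fit$rss, converged = fit$converged,
    seed = seed, config_hash = .config_hash(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "spr_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(fit = fit, constants = konst, report = report)
}
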