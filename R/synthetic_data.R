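#' NNK selection-library specification
#'
#' The combinatorial design of the display library: reads carry an
#' initiator ATG, 6-10 random NNK codons whose length distribution
#' follows the mixing ratio of the sub-libraries
#' (`0.0018 : 0.032 : 1 : 32 : 80` for lengths 6:7:8:9:10, normalized
#' internally), and a fixed tail encoding the `CGSGSGS` linker.
#'
#' @param length_weights named numeric vector of relative weights per
#'   random-region length.
#' @param scheme a [code_scheme] supplying the linker coding sequence.
#' @return an object of class `library_spec` with normalized
#'   `length_probs`.
#' @export
library_spec <- function(length_weights = c("6" = 0.0018, "7" = 0.032,
                                            "8" = 1, "9" = 32, "10" = 80),
                         scheme = code_scheme()) {
  stopifnot(is.numeric(length_weights), all(length_weights >= 0),
            any(length_weights > 0), !is.null(names(length_weights)))
  probs <- length_weights / sum(length_weights)
  structure(list(lengths = as.integer(names(length_weights)),
                 length_probs = unname(probs), scheme = scheme),
            class = "library_spec")
}

#' Sample naive library reads
#'
#' Draws i.i.d. reads: a random-region length from the library's
#' normalized length distribution, each random codon uniform over the
#' 32 NNK codons, flanked by the initiator ATG and the linker-coding
#' tail. Reproducible under `seed`.
#'
#' @param spec a [library_spec].
#' @param n number of reads; > 0.
#' @param seed RNG seed.
#' @return character vector of DNA reads.
#' @export
sample_library <- function(spec = library_spec(), n, seed = 1L) {
  stopifnot(inherits(spec, "library_spec"), n > 0)
  set.seed(seed)
  nnk <- .nnk_codons()
  linker_dna <- .linker_dna(spec$scheme)
  lens <- sample(spec$lengths, n, replace = TRUE, prob = spec$length_probs)
  total_codons <- sum(lens)
  cods <- sample(nnk, total_codons, replace = TRUE)
  idx_end <- cumsum(lens)
  idx_start <- idx_end - lens + 1L
  regions <- vapply(seq_len(n), function(i)
    paste0(cods[idx_start[i]:idx_end[i]], collapse = ""), character(1L))
  paste0("ATG", regions, linker_dna)
}

# linker-coding DNA under a scheme (first synonymous NNK codon per residue)
.linker_dna <- function(scheme) {
  nnk <- .nnk_codons()
  aa_by_codon <- scheme$codon_table[nnk]
  codons_for <- lapply(split(nnk, aa_by_codon), sort)
  paste0(vapply(strsplit(scheme$linker_peptide, "")[[1L]],
                function(a) codons_for[[a]][1L], character(1L)),
         collapse = "")
}

#' Selection-simulation configuration
#'
#' @param rounds number of selection rounds.
#' @param reads_per_round reads sequenced per round.
#' @param winners data frame with columns `peptide` and `fitness`
#'   (per-round multiplicative advantage; neutral = 1).
#' @param warhead_wash_survival fraction of warhead-free template mass
#'   surviving the denaturing washes each round, in `[0, 1]`.
#' @param washes_enabled apply the denaturing-wash penalty.
#' @param pool_size number of distinct naive background sequences.
#' @param seed RNG seed.
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(rounds = 5L, reads_per_round = 50000L,
                             winners = NULL, warhead_wash_survival = 0.01,
                             washes_enabled = TRUE, pool_size = 5000L,
                             seed = 1L) {
  if (is.null(winners))
    winners <- data.frame(peptide = character(), fitness = numeric())
  stopifnot(rounds >= 1L, reads_per_round >= 1L,
            all(winners$fitness >= 0),
            warhead_wash_survival >= 0, warhead_wash_survival <= 1)
  structure(list(rounds = as.integer(rounds),
                 reads_per_round = as.integer(reads_per_round),
                 winners = winners,
                 warhead_wash_survival = warhead_wash_survival,
                 washes_enabled = isTRUE(washes_enabled),
                 pool_size = as.integer(pool_size), seed = as.integer(seed)),
            class = "selection_config")
}

#' Strong-selection preset
#'
#' Five rounds, 50,000 reads per round, denaturing washes retaining 1%
#' of warhead-free template mass, and six warhead-bearing winner
#' peptides with a moderate (2.5-3x) per-round fitness advantage. This
#' is the regime reported for covalent selections: the warhead-free
#' fraction collapses after round one, while winner families climb
#' round over round yet remain individually low-abundance — the
#' moderate advantage keeps them below pool saturation within five
#' rounds, so every trajectory rises monotonically.
#'
#' @param seed RNG seed.
#' @return a [selection_config].
#' @export
strong_selection_config <- function(seed = 1L) {
  winners <- data.frame(
    peptide = c("yLD2HYSSKLY", "yIWGL2D2S", "ySKYD2RSPRD",
                "yVYS2KEWKY", "yWY2NWDFNKR", "yRD2HYRHPKY"),
    fitness = c(3, 2.5, 2.8, 2.5, 2.8, 2.5))
  selection_config(rounds = 5L, reads_per_round = 50000L, winners = winners,
                   warhead_wash_survival = 0.01, washes_enabled = TRUE,
                   pool_size = 5000L, seed = seed)
}

#' Simulate rounds of covalent mRNA-display selection
#'
#' Deterministic multiplicative-fitness model with multinomial
#' sequencing noise: the template pool starts as `pool_size` naive
#' library sequences (each with equal mass) plus the configured winner
#' peptides; each round multiplies every sequence's mass by its fitness
#' and, when denaturing washes are enabled, by the wash-survival factor
#' if its peptide lacks the warhead; reads are then drawn
#' multinomially. In `expectation` mode the resampling step is skipped
#' and expected read counts are emitted instead (rounded to integers
#' for tabulation).
#'
#' @param config a [selection_config].
#' @param spec a [library_spec] for the naive background.
#' @param out_dir if non-`NULL`, write one FASTQ per round (plus
#'   `round0` = the input pool sample) and `truth_ledger.json` there.
#' @param expectation emit expected counts instead of multinomial
#'   samples.
#' @return list with `reads` (list of per-round character vectors,
#'   `round0` first), `ledger` (true per-round frequencies, emission
#'   counts, warhead-free mass fraction and recovery fraction per
#'   round), and `fastq_paths` when `out_dir` is given.
#' @export
evolve_selection <- function(config, spec = library_spec(), out_dir = NULL,
                             expectation = FALSE) {
  stopifnot(inherits(config, "selection_config"))
  pool_dna <- sample_library(spec, config$pool_size, seed = config$seed)
  set.seed(config$seed + 1L)
  winner_dna <- if (nrow(config$winners))
    reverse_translate(config$winners$peptide, spec$scheme) else character(0)
  dna <- c(pool_dna, winner_dna)
  rec <- decode_reads(dna, spec$scheme)
  fitness <- rep(1, length(dna))
  if (nrow(config$winners)) {
    widx <- length(pool_dna) + seq_len(nrow(config$winners))
    fitness[widx] <- config$winners$fitness
  }
  has_wh <- rec$has_warhead
  mass <- rep(1, length(dna))
  mass <- mass / sum(mass)

  draw <- function(p, label) {
    if (expectation) {
      cnt <- round(p * config$reads_per_round)
    } else {
      cnt <- as.integer(stats::rmultinom(1L, config$reads_per_round, p))
    }
    rep(seq_along(dna), cnt)
  }

  set.seed(config$seed + 2L)
  reads <- list()
  ledger_rounds <- list()
  idx0 <- draw(mass, "round0")
  reads[["round0"]] <- dna[idx0]
  ledger_rounds[["round0"]] <- list(
    true_freq = mass, warhead_free_mass = sum(mass[!has_wh]),
    recovery = 1, emitted = length(idx0))
  for (r in seq_len(config$rounds)) {
    w <- mass * fitness
    if (config$washes_enabled)
      w[!has_wh] <- w[!has_wh] * config$warhead_wash_survival
    if (sum(w) <= 0) stop("all-zero fitness mass at round ", r)
    recovery <- sum(w)        # pre-normalization mass = captured fraction
    mass <- w / sum(w)
    idx <- draw(mass, paste0("round", r))
    rn <- paste0("round", r)
    reads[[rn]] <- dna[idx]
    ledger_rounds[[rn]] <- list(
      true_freq = mass, warhead_free_mass = sum(mass[!has_wh]),
      recovery = recovery, emitted = length(idx))
  }

  ledger <- list(
    seed = config$seed, pool_size = config$pool_size,
    reads_per_round = config$reads_per_round,
    washes_enabled = config$washes_enabled,
    warhead_wash_survival = config$warhead_wash_survival,
    winners = config$winners,
    peptides = rec$peptide, has_warhead = has_wh,
    rounds = lapply(ledger_rounds, function(x)
      x[c("warhead_free_mass", "recovery", "emitted")]))
  out <- list(reads = reads, ledger = ledger,
              truth = lapply(ledger_rounds, `[[`, "true_freq"),
              peptides = rec$peptide, has_warhead = has_wh)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(length(reads))
    for (i in seq_along(reads)) {
      paths[i] <- file.path(out_dir, paste0(names(reads)[i], ".fastq"))
      write_fastq(reads[[i]], paths[i], prefix = names(reads)[i])
    }
    names(paths) <- names(reads)
    jsonlite::write_json(ledger, file.path(out_dir, "truth_ledger.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    out$fastq_paths <- paths
  }
  out
}

#' Noise model for simulated assays
#'
#' @param plate_sigma additive Gaussian SD on normalized activity.
#' @param spr_sigma additive Gaussian SD on SPR response, RU.
#' @param spr_drift linear baseline drift, RU per second.
#' @param seed RNG seed.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(plate_sigma = 0, spr_sigma = 0, spr_drift = 0,
                        seed = 1L) {
  stopifnot(plate_sigma >= 0, spr_sigma >= 0)
  structure(list(plate_sigma = plate_sigma, spr_sigma = spr_sigma,
                 spr_drift = spr_drift, seed = as.integer(seed)),
            class = "noise_model")
}

#' Default quench-time kinetics plate design
#'
#' Nine final inhibitor concentrations from two interleaved 5-fold
#' dilution series (50 to 0.08 uM after the in-assay 10-fold dilution)
#' plus a no-inhibitor control, quenched at 15-minute intervals for
#' five timepoints.
#'
#' @return list with `concs_uM` (including the 0 control) and
#'   `times_min`.
#' @export
default_colder_design <- function() {
  list(concs_uM = c(50, 30, 10, 6, 2, 1.2, 0.4, 0.24, 0.08, 0),
       times_min = c(15, 30, 45, 60, 75))
}

#' Simulate a quench-time activity plate
#'
#' Activity at `(I, t)` is the ratio of inhibited to uninhibited
#' product accumulation, `P_I(t)/P_0(t)`, from the closed-form covalent
#' progress curves of the generating model, plus additive Gaussian
#' noise; the zero-concentration control row is 1 plus noise.
#'
#' @param truth a [krippendorff_model] (the generating parameters).
#' @param concs_uM inhibitor concentrations (0 allowed).
#' @param times_min quench times.
#' @param noise a [noise_model].
#' @param replicate replicate id.
#' @return an [activity_plate].
#' @export
simulate_colder_plate <- function(truth,
                                  concs_uM = default_colder_design()$concs_uM,
                                  times_min = default_colder_design()$times_min,
                                  noise = noise_model(),
                                  replicate = "r1") {
  stopifnot(inherits(truth, "krippendorff_model"), length(concs_uM) >= 1L,
            length(times_min) >= 1L)
  set.seed(noise$seed)
  m <- matrix(NA_real_, length(concs_uM), length(times_min))
  p0 <- progress_curve(0, truth, 1, times_min)
  for (i in seq_along(concs_uM))
    m[i, ] <- progress_curve(concs_uM[i], truth, 1, times_min) / p0
  if (noise$plate_sigma > 0)
    m <- m + stats::rnorm(length(m), 0, noise$plate_sigma)
  m <- pmin(pmax(m, -0.2), 1.5)
  activity_plate(concs_uM, times_min, m, replicate = replicate)
}

#' Simulate a noisy sensorgram
#'
#' Wraps [simulate_two_state] and adds Gaussian read noise and a linear
#' baseline drift; with zero noise the output is identical to the clean
#' simulation.
#'
#' @param params a [two_state_params].
#' @param scheme an [injection_scheme].
#' @param noise a [noise_model].
#' @param times output times, s.
#' @return a `sensorgram`.
#' @export
simulate_sensorgram_noisy <- function(params, scheme, noise = noise_model(),
                                      times = NULL) {
  gram <- simulate_two_state(params, scheme, times)
  set.seed(noise$seed)
  resp <- gram$response
  if (noise$spr_sigma > 0)
    resp <- resp + stats::rnorm(length(resp), 0, noise$spr_sigma)
  if (noise$spr_drift != 0)
    resp <- resp + noise$spr_drift * gram$times
  gram$response <- resp
  gram
}
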