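#' Reprogrammed genetic code scheme
#'
#' Translation scheme of the selection library: the initiator ATG is
#' reassigned to N-chloroacetyl-D-tyrosine (symbol `y`), every internal
#' Met (ATG) codon to the electrophilic warhead amino acid (symbol `2`),
#' all other codons follow the standard nuclear code, and reads carry a
#' C-terminal linker encoding `CGSGSGS` whose first Cys is the
#' cyclization point. The amber codon TAG is vacant in the reprogrammed
#' translation system and is flagged as a premature stop.
#'
#' @param initiator_symbol character for the reprogrammed initiator.
#' @param warhead_symbol character for internal-Met reassignment.
#' @param linker_peptide the C-terminal linker peptide.
#' @param cys_rich_threshold random regions with more than this many Cys
#'   are flagged `cys_rich`.
#' @return an object of class `code_scheme`.
#' @export
code_scheme <- function(initiator_symbol = "y", warhead_symbol = "2",
                        linker_peptide = "CGSGSGS", cys_rich_threshold = 3L) {
  tab <- Biostrings::GENETIC_CODE
  structure(list(initiator_symbol = initiator_symbol,
                 warhead_symbol = warhead_symbol,
                 linker_peptide = linker_peptide,
                 cys_rich_threshold = cys_rich_threshold,
                 codon_table = tab),
            class = "code_scheme")
}

# the 32 NNK codons (third base G or T)
.nnk_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(as.vector(outer(b, b, paste0)), c("G", "T"), paste0))
}

#' Check NNK degeneracy of a random region
#'
#' `TRUE` iff every codon's third base is G or T (the K of NNK).
#'
#' @param dna_random_region DNA string(s), length divisible by 3.
#' @return logical vector.
#' @export
validate_nnk <- function(dna_random_region) {
  stopifnot(is.character(dna_random_region))
  if (any(nchar(dna_random_region) %% 3 != 0))
    stop("random-region length must be divisible by 3")
  vapply(dna_random_region, function(s) {
    if (nchar(s) == 0L) return(TRUE)
    third <- substring(s, seq(3, nchar(s), 3), seq(3, nchar(s), 3))
    all(third %in% c("G", "T"))
  }, logical(1L), USE.NAMES = FALSE)
}

# translate DNA strings under the reprogrammed code, vectorized;
# returns NA for reads that do not start with ATG or are too short
.translate_reprogrammed <- function(dna, scheme) {
  n <- nchar(dna)
  ncod <- n %/% 3L
  out <- rep(NA_character_, length(dna))
  ok <- substr(dna, 1L, 3L) == "ATG" & ncod >= 7L
  for (len in unique(ncod[ok])) {
    idx <- which(ok & ncod == len)
    starts <- seq(1L, by = 3L, length.out = len)
    codmat <- matrix(NA_character_, length(idx), len)
    for (j in seq_len(len))
      codmat[, j] <- substr(dna[idx], starts[j], starts[j] + 2L)
    aamat <- matrix(scheme$codon_table[codmat], length(idx), len)
    aamat[is.na(aamat)] <- "X"
    aamat[aamat == "M"] <- scheme$warhead_symbol   # internal Met -> warhead
    aamat[, 1L] <- scheme$initiator_symbol         # initiator ATG
    out[idx] <- apply(aamat, 1L, paste0, collapse = "")
  }
  out
}

#' Decode selection reads into peptide records
#'
#' Translates each read from its initiator ATG under the reprogrammed
#' code (see [code_scheme]), locates the `CGSGSGS` linker by translated
#' match (its first Cys is the cyclization point), and derives the
#' random-region length, warhead content and validity flags. When the
#' canonical linker is absent (mutated linker variants), the first Cys
#' after at least 6 random codons is used as the cyclization point and
#' the record is flagged `linker_lost`.
#'
#' Flags: `valid` (decodable, 6-10 random codons, linker present),
#' `linker_lost`, `premature_stop` (amber TAG inside the random region;
#' such reads are excluded from peptide statistics), `non_NNK` (a
#' random-region codon off the NNK design), `cys_rich` (more Cys in the
#' random region than the scheme's threshold).
#'
#' @param dna character vector of reads over A/C/G/T, already trimmed to
#'   start at the initiator codon.
#' @param scheme a [code_scheme].
#' @return a data frame of class `peptide_records` with columns `dna`,
#'   `peptide`, `random_region_length`, `has_warhead`, `valid`,
#'   `linker_lost`, `premature_stop`, `non_NNK`, `cys_rich`.
#' @export
decode_reads <- function(dna, scheme = code_scheme()) {
  stopifnot(is.character(dna), inherits(scheme, "code_scheme"))
  dna <- toupper(dna)
  pep_full <- .translate_reprogrammed(dna, scheme)
  n <- length(dna)
  peptide <- rep(NA_character_, n)
  rlen <- rep(NA_integer_, n)
  has_warhead <- rep(FALSE, n)
  valid <- rep(FALSE, n)
  linker_lost <- rep(FALSE, n)
  premature <- rep(FALSE, n)
  non_nnk <- rep(FALSE, n)
  cys_rich <- rep(FALSE, n)

  dec <- which(!is.na(pep_full))
  if (length(dec)) {
    pf <- pep_full[dec]
    # linker position in the translated string (after the initiator)
    lpos <- as.integer(regexpr(scheme$linker_peptide, pf, fixed = TRUE))
    # fallback: first Cys after >= 6 random codons (positions 2..7 are random)
    fb <- lpos < 0L
    if (any(fb)) {
      cpos <- as.integer(regexpr("C", substring(pf[fb], 8L), fixed = TRUE))
      lpos[fb] <- ifelse(cpos > 0L, cpos + 7L, -1L)
      linker_lost[dec[fb]] <- TRUE
    }
    found <- lpos > 1L
    rl <- ifelse(found, lpos - 2L, NA_integer_)
    random <- ifelse(found, substring(pf, 2L, pmax(lpos - 1L, 1L)), NA)
    peptide[dec] <- pf
    rlen[dec] <- rl
    has_warhead[dec] <- found &
      grepl(scheme$warhead_symbol, random, fixed = TRUE)
    premature[dec] <- found & grepl("*", random, fixed = TRUE)
    cys_rich[dec] <- found &
      (nchar(random) - nchar(gsub("C", "", random, fixed = TRUE))) >
        scheme$cys_rich_threshold
    # NNK check on the random-region DNA
    ok_rl <- which(found & !is.na(rl) & rl >= 1L)
    if (length(ok_rl)) {
      rr_dna <- substr(dna[dec[ok_rl]], 4L, 3L + 3L * rl[ok_rl])
      non_nnk[dec[ok_rl]] <- !validate_nnk(rr_dna)
    }
    valid[dec] <- found & !linker_lost[dec] & !premature[dec] &
      !is.na(rl) & rl >= 6L & rl <= 10L
  }
  out <- data.frame(dna = dna, peptide = peptide,
                    random_region_length = rlen, has_warhead = has_warhead,
                    valid = valid, linker_lost = linker_lost,
                    premature_stop = premature, non_NNK = non_nnk,
                    cys_rich = cys_rich, stringsAsFactors = FALSE)
  class(out) <- c("peptide_records", "data.frame")
  out
}

#' @rdname decode_reads
#' @export
decode_read <- function(dna, scheme = code_scheme()) {
  decode_reads(dna, scheme)[1L, ]
}

#' Reverse-translate a peptide into an NNK-compliant read
#'
#' Builds a DNA read for a peptide over the reprogrammed alphabet:
#' initiator symbol -> ATG, warhead symbol -> ATG, other residues ->
#' an NNK codon encoding them (sampled uniformly among the synonymous
#' NNK codons, or the first alphabetically when `deterministic`),
#' followed by the fixed linker-coding sequence. The input may or may
#' not include the initiator symbol and/or linker peptide; both are
#' handled.
#'
#' @param peptide peptide string(s), e.g. `"yLD2HYSSKLY"`.
#' @param scheme a [code_scheme].
#' @param deterministic pick the alphabetically first NNK codon per
#'   residue instead of sampling.
#' @return character vector of DNA reads.
#' @export
reverse_translate <- function(peptide, scheme = code_scheme(),
                              deterministic = FALSE) {
  stopifnot(is.character(peptide))
  nnk <- .nnk_codons()
  aa_by_codon <- scheme$codon_table[nnk]
  codons_for <- split(nnk, aa_by_codon)
  codons_for <- lapply(codons_for, sort)
  linker_dna <- paste0(vapply(strsplit(scheme$linker_peptide, "")[[1L]],
                              function(a) codons_for[[a]][1L], character(1L)),
                       collapse = "")
  vapply(peptide, function(p) {
    res <- strsplit(p, "")[[1L]]
    if (length(res) && res[1L] == scheme$initiator_symbol)
      res <- res[-1L]
    # strip a trailing linker if the caller included it
    lp <- scheme$linker_peptide
    pl <- paste0(res, collapse = "")
    if (nchar(pl) >= nchar(lp) &&
        substring(pl, nchar(pl) - nchar(lp) + 1L) == lp)
      res <- res[seq_len(length(res) - nchar(lp))]
    cods <- vapply(res, function(a) {
      if (a == scheme$warhead_symbol) return("ATG")
      cc <- codons_for[[a]]
      if (is.null(cc)) stop("residue not NNK-encodable: ", a)
      if (deterministic) cc[1L] else sample(cc, 1L)
    }, character(1L))
    paste0("ATG", paste0(cods, collapse = ""), linker_dna)
  }, character(1L), USE.NAMES = FALSE)
}

#' Count peptides per selection round
#'
#' Reads one FASTQ per round, decodes the reads (see [decode_reads]),
#' and counts identical peptide strings among valid records. Rows are
#' ordered by count (descending) with lexicographic tie-break, which
#' makes ranked tables deterministic. Base qualities are ignored.
#'
#' @param fastq_per_round character vector of FASTQ paths, one per
#'   round, in round order; alternatively a list of character vectors of
#'   reads (already in memory).
#' @param scheme a [code_scheme].
#' @param round_names optional names; defaults to `round1`, ...
#' @return an object of class `round_counts`: list with `rounds` (one
#'   data frame per round: `peptide`, `count`, `frequency`, `rank`,
#'   `has_warhead`), `totals` (valid reads per round), `raw_totals`
#'   (all reads per round).
#' @export
tabulate_rounds <- function(fastq_per_round, scheme = code_scheme(),
                            round_names = NULL) {
  reads <- if (is.list(fastq_per_round)) fastq_per_round
    else lapply(fastq_per_round, read_fastq_reads)
  if (length(reads) < 1L) stop("need at least one round")
  if (is.null(round_names))
    round_names <- paste0("round", seq_along(reads))
  rounds <- vector("list", length(reads))
  totals <- integer(length(reads))
  raw_totals <- integer(length(reads))
  for (r in seq_along(reads)) {
    rr <- reads[[r]]
    raw_totals[r] <- length(rr)
    if (length(rr) == 0L) {
      warning("round ", round_names[r], " is empty")
      rounds[[r]] <- data.frame(peptide = character(), count = integer(),
                                frequency = numeric(), rank = integer(),
                                has_warhead = logical())
      next
    }
    # decode unique reads once; multiply back by read multiplicity
    tab <- table(rr)
    rec <- decode_reads(names(tab), scheme)
    keep <- rec$valid
    if (!any(keep)) {
      rounds[[r]] <- data.frame(peptide = character(), count = integer(),
                                frequency = numeric(), rank = integer(),
                                has_warhead = logical())
      next
    }
    cnt <- as.integer(tab)[keep]
    agg <- stats::aggregate(cnt, list(peptide = rec$peptide[keep]), sum)
    wh <- rec$has_warhead[keep][!duplicated(rec$peptide[keep])]
    names(wh) <- rec$peptide[keep][!duplicated(rec$peptide[keep])]
    ord <- order(-agg$x, agg$peptide, method = "radix")
    df <- data.frame(peptide = agg$peptide[ord], count = agg$x[ord],
                     stringsAsFactors = FALSE)
    df$frequency <- df$count / sum(df$count)
    df$rank <- seq_len(nrow(df))
    df$has_warhead <- unname(wh[df$peptide])
    rounds[[r]] <- df
    totals[r] <- sum(df$count)
  }
  names(rounds) <- round_names
  structure(list(rounds = rounds, totals = totals, raw_totals = raw_totals),
            class = "round_counts")
}

#' Fraction of reads lacking the encoded warhead
#'
#' Percentage of a round's reads whose peptide contains no internal
#' warhead residue. Covalent selections with denaturing washes collapse
#' this fraction after the first round. The default weights by read
#' count; `weight = "unique"` counts each distinct peptide once.
#'
#' @param counts a [tabulate_rounds] result.
#' @param r round index.
#' @param weight `"reads"` (default) or `"unique"`.
#' @return percentage in `[0, 100]`.
#' @export
warhead_missing_fraction <- function(counts, r, weight = c("reads", "unique")) {
  stopifnot(inherits(counts, "round_counts"))
  weight <- match.arg(weight)
  if (r < 1L || r > length(counts$rounds)) stop("no such round: ", r)
  df <- counts$rounds[[r]]
  if (nrow(df) == 0L || sum(df$count) == 0L)
    stop("round ", r, " has no decoded reads")
  if (weight == "reads")
    100 * sum(df$count[!df$has_warhead]) / sum(df$count)
  else
    100 * sum(!df$has_warhead) / nrow(df)
}

#' Per-round enrichment trajectories
#'
#' Frequency, rank, and round-over-round fold change for chosen
#' peptides. Fold changes from a zero count use add-one smoothing on
#' the counts of both rounds.
#'
#' @param counts a [tabulate_rounds] result.
#' @param peptides peptides to track (unknown peptides yield all-zero
#'   rows, not an error).
#' @return an `enrichment_table`: data frame with one row per
#'   (peptide, round): `peptide`, `round`, `count`, `frequency`,
#'   `rank` (NA when absent), `fold_change` (vs previous round; NA for
#'   the first round).
#' @export
enrichment_trajectory <- function(counts, peptides) {
  stopifnot(inherits(counts, "round_counts"), length(peptides) >= 1L)
  R <- length(counts$rounds)
  out <- expand.grid(peptide = peptides,
                     round = seq_len(R), stringsAsFactors = FALSE)
  out$count <- 0L; out$frequency <- 0; out$rank <- NA_integer_
  for (r in seq_len(R)) {
    df <- counts$rounds[[r]]
    m <- match(out$peptide[out$round == r], df$peptide)
    sel <- which(out$round == r)
    out$count[sel] <- ifelse(is.na(m), 0L, df$count[m])
    out$frequency[sel] <- ifelse(is.na(m), 0, df$frequency[m])
    out$rank[sel] <- df$rank[m]
  }
  out$fold_change <- NA_real_
  for (r in 2:max(2L, R)) {
    if (r > R) break
    sel <- which(out$round == r)
    prev <- which(out$round == r - 1L)
    n_prev <- sum(counts$rounds[[r - 1L]]$count)
    n_cur <- sum(counts$rounds[[r]]$count)
    f_prev <- out$frequency[prev]
    f_cur <- out$frequency[sel]
    smooth <- f_prev == 0 | f_cur == 0
    fc <- f_cur / f_prev
    fc[smooth] <- ((out$count[sel][smooth] + 1) / (n_cur + 1)) /
      ((out$count[prev][smooth] + 1) / (n_prev + 1))
    out$fold_change[sel] <- fc
  }
  class(out) <- c("enrichment_table", "data.frame")
  out
}

# pairwise peptide distance: Hamming for equal lengths, edit distance
# otherwise (generalized Levenshtein via adist)
.pep_dist <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  } else {
    as.integer(utils::adist(a, b))
  }
}

#' Greedy single-linkage clustering of peptide families
#'
#' Clusters peptides into families: sequences are processed in count
#' order (descending, lexicographic tie-break); each joins every
#' existing family containing a member within `max_dist` (merging those
#' families, so the result equals the connected components of the
#' threshold graph), or founds a new family seeded by itself. Distance
#' is Hamming for equal-length pairs and edit distance otherwise.
#'
#' @param peptides character vector.
#' @param counts read counts (defaults to 1 each).
#' @param max_dist distance threshold for family membership.
#' @return data frame `peptide`, `count`, `family` (integer id, numbered
#'   by the highest-count seed), `seed` (family representative).
#' @export
cluster_families <- function(peptides, counts = NULL, max_dist = 2L) {
  stopifnot(is.character(peptides), length(peptides) >= 1L)
  if (is.null(counts)) counts <- rep(1L, length(peptides))
  stopifnot(length(counts) == length(peptides))
  ord <- order(-counts, peptides, method = "radix")
  p <- peptides[ord]; cnt <- counts[ord]
  fam <- integer(length(p))
  members <- list()
  for (i in seq_along(p)) {
    hit <- integer(0)
    for (f in seq_along(members)) {
      if (any(vapply(members[[f]], function(m) .pep_dist(p[i], m) <= max_dist,
                     logical(1L)))) hit <- c(hit, f)
    }
    if (length(hit) == 0L) {
      members[[length(members) + 1L]] <- p[i]
      fam[i] <- length(members)
    } else {
      keep <- hit[1L]
      if (length(hit) > 1L) {
        for (f in rev(hit[-1L])) {
          members[[keep]] <- c(members[[keep]], members[[f]])
          fam[fam == f] <- keep
          fam[fam > f] <- fam[fam > f] - 1L
          members[[f]] <- NULL
        }
      }
      members[[keep]] <- c(members[[keep]], p[i])
      fam[i] <- keep
    }
  }
  seeds <- vapply(seq_along(members), function(f) p[which(fam == f)[1L]],
                  character(1L))
  out <- data.frame(peptide = p, count = cnt, family = fam,
                    seed = seeds[fam], stringsAsFactors = FALSE)
  out[match(peptides, out$peptide), , drop = FALSE]
}

#' Library recovery percentage
#'
#' qPCR-style recovery arithmetic: recovered template copies as a
#' percentage of the input copies.
#'
#' @param recovered_copies recovered template copies; >= 0.
#' @param input_copies input copies; > 0.
#' @return percentage.
#' @export
recovery_percent <- function(recovered_copies, input_copies) {
  stopifnot(is.numeric(recovered_copies), is.numeric(input_copies))
  if (any(input_copies <= 0)) stop("input_copies must be positive")
  if (any(recovered_copies < 0)) stop("recovered_copies must be non-negative")
  100 * recovered_copies / input_copies
}
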