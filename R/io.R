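#' Read selection reads from a FASTQ file
#'
#' Returns the read sequences as a character vector; base qualities are
#' ignored throughout the selection analysis. Gzipped files are handled
#' transparently.
#'
#' @param path FASTQ path.
#' @return character vector of reads.
#' @export
read_fastq_reads <- function(path) {
  if (!file.exists(path)) stop("no such FASTQ: ", path)
  info <- file.info(path)
  if (info$size == 0) return(character(0))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(x)
}

#' Write reads to a FASTQ file
#'
#' Emits one record per read with a running identifier and a constant
#' quality string (qualities are unused downstream).
#'
#' @param reads character vector of DNA reads.
#' @param path output path.
#' @param prefix read-identifier prefix.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, prefix = "read") {
  ids <- sprintf("@%s_%06d", prefix, seq_along(reads))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1L))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(ids, reads, "+", qual, sep = "\n"), con)
  invisible(path)
}

#' Read an activity plate from CSV
#'
#' Accepts the wide format (`conc_uM` column then one `t_<min>` column
#' per quench time) or the long format
#' (`conc_uM,time_min,activity,replicate`).
#'
#' @param path CSV path.
#' @param replicate replicate id for wide-format files.
#' @return an [activity_plate] (long-format files with several
#'   replicates give a list of plates).
#' @export
read_plate_csv <- function(path, replicate = "r1") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("conc_uM", "time_min", "activity") %in% names(df))) {
    reps <- if ("replicate" %in% names(df)) unique(df$replicate) else "r1"
    plates <- lapply(reps, function(rp) {
      d <- if ("replicate" %in% names(df)) df[df$replicate == rp, ] else df
      concs <- sort(unique(d$conc_uM), decreasing = TRUE)
      times <- sort(unique(d$time_min))
      m <- matrix(NA_real_, length(concs), length(times))
      m[cbind(match(d$conc_uM, concs), match(d$time_min, times))] <- d$activity
      activity_plate(concs, times, m, replicate = as.character(rp))
    })
    if (length(plates) == 1L) plates[[1L]] else plates
  } else if ("conc_uM" %in% names(df)) {
    tcols <- grep("^t_", names(df), value = TRUE)
    if (length(tcols) == 0L)
      stop("malformed plate CSV (no t_<min> columns): ", path)
    times <- as.numeric(sub("^t_", "", tcols))
    ord <- order(times)
    activity_plate(df$conc_uM, times[ord],
                   as.matrix(df[, tcols[ord], drop = FALSE]),
                   replicate = replicate)
  } else {
    stop("malformed plate CSV (no conc_uM column): ", path)
  }
}

#' Write an activity plate to wide-format CSV
#'
#' @param plate an [activity_plate].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  stopifnot(inherits(plate, "activity_plate"))
  df <- data.frame(conc_uM = plate$inhibitor_concs)
  for (j in seq_along(plate$quench_times))
    df[[sprintf("t_%g", plate$quench_times[j])]] <- plate$activity[, j]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write sensorgram CSV (`time_s,response_RU`)
#'
#' @param path CSV path.
#' @param scheme an [injection_scheme] to attach (reading), or taken
#'   from the sensorgram (writing).
#' @return a [simulate_two_state] style `sensorgram` (reading).
#' @name sensorgram_csv
#' @export
read_sensorgram_csv <- function(path, scheme) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "response_RU") %in% names(df)))
  structure(list(times = df$time_s, response = df$response_RU,
                 scheme = scheme), class = "sensorgram")
}

#' @rdname sensorgram_csv
#' @param gram a `sensorgram`.
#' @export
write_sensorgram_csv <- function(gram, path) {
  utils::write.csv(data.frame(time_s = gram$times,
                              response_RU = gram$response),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write an injection scheme as YAML
#'
#' The YAML carries a list of `{conc_M, start_s, stop_s}` segments plus
#' `final_dissociation_s`.
#'
#' @param path YAML path.
#' @name scheme_yaml
#' @export
read_scheme_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  seg <- do.call(rbind, lapply(y$segments, function(s)
    data.frame(conc_M = s$conc_M, start_s = s$start_s, stop_s = s$stop_s)))
  injection_scheme(segments = seg, final_dissoc_s = y$final_dissociation_s)
}

#' @rdname scheme_yaml
#' @param scheme an [injection_scheme].
#' @export
write_scheme_yaml <- function(scheme, path) {
  y <- list(segments = lapply(seq_len(nrow(scheme$segments)), function(i)
    list(conc_M = scheme$segments$conc_M[i],
         start_s = scheme$segments$start_s[i],
         stop_s = scheme$segments$stop_s[i])),
    final_dissociation_s = scheme$final_dissociation)
  yaml::write_yaml(y, path)
  invisible(path)
}

# stable hash of a configuration list (md5 of its canonical JSON)
.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}
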