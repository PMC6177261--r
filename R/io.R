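## TSV/JSON dialects used across the pipeline: tab-separated, '#' comment
## lines, header row required. Readers raise errors naming the file and
## offending field.

.read_tsv <- function(file, required) {
  if (!file.exists(file)) stop("no such file: ", file)
  df <- tryCatch(
    utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", file, ": ",
                             conditionMessage(e)))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(file, ": missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

.write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a PBM probe table (TSV)
#'
#' Required columns: `probe_id`, `sequence`, `intensity`; optional
#' `replicate`.
#'
#' @param file Path to a tab-separated probe table.
#' @return Validated probe data frame.
#' @export
read_probe_table <- function(file) {
  df <- .read_tsv(file, c("probe_id", "sequence", "intensity"))
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  bad <- which(!is.finite(df$intensity) | df$intensity <= 0)
  if (length(bad))
    stop(file, ": non-positive or non-finite intensity at data row ",
         bad[1], " (field 'intensity')")
  bad <- which(grepl("[^ACGT]", df$sequence))
  if (length(bad))
    stop(file, ": invalid probe sequence at data row ", bad[1],
         " (field 'sequence')")
  df
}

#' Write a PBM probe table (TSV)
#' @param probes Probe data frame.
#' @param file Output path.
#' @export
write_probe_table <- function(probes, file) .write_tsv(probes, file)

#' Read an equilibrium titration table (TSV)
#'
#' Required columns: `protein_M`, `fraction_bound`; optional `replicate`.
#' The DNA concentration is given separately (it is a property of the
#' assay, not of a row).
#'
#' @param file Path to a tab-separated titration table.
#' @param D Labelled-DNA concentration (M).
#' @param motif Optional motif label.
#' @return A [titration_series()].
#' @export
read_titration <- function(file, D, motif = NA_character_) {
  df <- .read_tsv(file, c("protein_M", "fraction_bound"))
  bad <- which(!is.finite(df$protein_M) | df$protein_M < 0)
  if (length(bad))
    stop(file, ": invalid protein concentration at data row ", bad[1],
         " (field 'protein_M')")
  titration_series(df$protein_M, df$fraction_bound, D, motif = motif,
                   replicate = if ("replicate" %in% names(df))
                     df$replicate else NULL)
}

#' Write a titration series (TSV)
#' @param x A `titration_series`.
#' @param file Output path.
#' @export
write_titration <- function(x, file) {
  .write_tsv(data.frame(protein_M = x$P, fraction_bound = x$F_obs,
                        replicate = x$replicate), file)
}

#' Read SPR sensorgrams (TSV)
#'
#' Required columns: `time_s`, `response_RU`, `conc_M`, `phase`
#' (`association`/`dissociation`). Rows are split into one sensorgram per
#' (concentration, phase).
#'
#' @param file Path to a tab-separated sensorgram table.
#' @return List of [sensorgram()]s.
#' @export
read_sensorgrams <- function(file) {
  df <- .read_tsv(file, c("time_s", "response_RU", "conc_M", "phase"))
  bad <- which(!df$phase %in% c("association", "dissociation"))
  if (length(bad))
    stop(file, ": invalid phase '", df$phase[bad[1]], "' at data row ",
         bad[1], " (field 'phase')")
  sp <- split(df, list(df$conc_M, df$phase), drop = TRUE)
  lapply(unname(sp), function(d)
    sensorgram(d$time_s, d$response_RU, d$conc_M[1], d$phase[1]))
}

#' Write sensorgrams (TSV)
#' @param curves List of `sensorgram`s.
#' @param file Output path.
#' @export
write_sensorgrams <- function(curves, file) {
  df <- do.call(rbind, lapply(curves, function(sg)
    data.frame(time_s = sg$t, response_RU = sg$R,
               conc_M = attr(sg, "c0"), phase = attr(sg, "phase"))))
  .write_tsv(df, file)
}

#' Write a k-mer score table (TSV)
#' @param x A `kmer_score_table`.
#' @param file Output path.
#' @export
write_kmer_scores <- function(x, file) {
  .write_tsv(as.data.frame(x), file)
}

#' Read a k-mer score table (TSV)
#' @param file Path; `k` is inferred from the k-mer length.
#' @return A `kmer_score_table`.
#' @export
read_kmer_scores <- function(file) {
  df <- .read_tsv(file, c("kmer", "escore"))
  structure(df, k = nchar(df$kmer[1]),
            class = c("kmer_score_table", "data.frame"))
}

#' Serialize an energy model to JSON
#' @param model An `energy_model`.
#' @param file Output path.
#' @export
write_energy_model <- function(model, file) {
  jsonlite::write_json(
    list(L = model$L, eps = model$eps, mu = model$mu,
         beta = model$beta, bg = model$bg),
    file, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(file)
}

#' Read an energy model from JSON
#' @param file Path written by [write_energy_model()].
#' @return An `energy_model`.
#' @export
read_energy_model <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  eps <- matrix(unlist(j$eps), nrow = j$L, byrow = FALSE)
  if (!is.null(dim(j$eps))) eps <- j$eps
  energy_model(eps, mu = j$mu, beta = j$beta, bg = j$bg)
}

#' Write a posterior table (TSV)
#'
#' One row per site: node, site, the 20 posterior probabilities, the ML
#' state and the AltAll state.
#'
#' @param posterior An `ancestral_posterior`.
#' @param seqs The matching `ancestral_sequence_set`.
#' @param file Output path.
#' @export
write_posterior_table <- function(posterior, seqs, file) {
  pp <- posterior$pp
  alt <- strsplit(seqs$altall, "")[[1]]
  df <- data.frame(node = posterior$node, site = seq_len(nrow(pp)),
                   round(pp, 6), ml_state = posterior$ml_state,
                   altall_state = alt, check.names = FALSE)
  .write_tsv(df, file)
}
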