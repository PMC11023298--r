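# Readers/writers for GWAS summary statistics, allele-frequency tables and
# posterior-sample matrices, plus allele harmonization across the three.

.col_aliases <- list(
  id = c("SNP", "ID", "RSID", "VARIANT_ID", "MARKERNAME", "MARKER"),
  effect_allele = c("A1", "EA", "EFFECT_ALLELE", "ALLELE1"),
  other_allele = c("A2", "OA", "OTHER_ALLELE", "ALLELE2", "ALLELE0", "REF"),
  beta = c("BETA", "B", "EFFECT", "LOG_ODDS", "LOGOR"),
  se = c("SE", "STDERR", "STDERRLOGOR"),
  n = c("N", "NEFF", "N_EFF", "NTOTAL"),
  freq = c("FRQ", "EAF", "FREQ", "AF", "A1FREQ", "EFFECT_ALLELE_FREQ"),
  allele = c("ALLELE", "A1", "EA", "EFFECT_ALLELE", "REF")
)

resolve_column <- function(cols, field, column_map, required = TRUE) {
  if (!is.null(column_map[[field]])) {
    hit <- match(toupper(column_map[[field]]), toupper(cols))
    if (is.na(hit)) {
      stop("mapped column '", column_map[[field]], "' for field '", field,
           "' not found; file has: ", paste(cols, collapse = ", "),
           call. = FALSE)
    }
    return(cols[hit])
  }
  hit <- match(.col_aliases[[field]], toupper(cols))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) {
    if (required) {
      stop("cannot resolve a '", field, "' column; file has: ",
           paste(cols, collapse = ", "), "; recognized aliases: ",
           paste(.col_aliases[[field]], collapse = ", "), call. = FALSE)
    }
    return(NULL)
  }
  cols[hit[1]]
}

log_msg <- function(...) message("[pgsdiff] ", ...)

#' Read GWAS summary statistics from a tab-separated file
#'
#' Columns are auto-detected from common GWAS header conventions (SNP/ID,
#' A1/EA, A2/OA, BETA, SE, N, FRQ/EAF) or supplied explicitly through
#' `column_map`. The per-SNP sampling variance is `SE^2` when a standard
#' error column is present, otherwise `1 / (2 N f (1 - f))` from the sample
#' size and effect-allele frequency. Rows with missing or invalid fields
#' (e.g. frequency at 0 or 1) are dropped with a logged reason.
#'
#' @param path Path to a (possibly gzipped) tab- or whitespace-separated file.
#' @param column_map Optional named list overriding auto-detection; names
#'   among `id`, `effect_allele`, `other_allele`, `beta`, `se`, `n`, `freq`.
#' @return A data.frame with columns `id`, `effect_allele`, `other_allele`,
#'   `beta_hat`, `s2`, and where available `freq` and `n`.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, data.table = FALSE)
  cols <- names(dt)
  id_col <- resolve_column(cols, "id", column_map)
  ea_col <- resolve_column(cols, "effect_allele", column_map)
  oa_col <- resolve_column(cols, "other_allele", column_map)
  beta_col <- resolve_column(cols, "beta", column_map)
  se_col <- resolve_column(cols, "se", column_map, required = FALSE)
  n_col <- resolve_column(cols, "n", column_map, required = FALSE)
  freq_col <- resolve_column(cols, "freq", column_map, required = FALSE)
  if (is.null(se_col) && (is.null(n_col) || is.null(freq_col))) {
    stop("need either an SE column or both N and frequency columns; ",
         "file has: ", paste(cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(id = as.character(dt[[id_col]]),
                    effect_allele = toupper(as.character(dt[[ea_col]])),
                    other_allele = toupper(as.character(dt[[oa_col]])),
                    beta_hat = as.numeric(dt[[beta_col]]),
                    stringsAsFactors = FALSE)
  if (!is.null(freq_col)) out$freq <- as.numeric(dt[[freq_col]])
  if (!is.null(n_col)) out$n <- as.numeric(dt[[n_col]])

  bad <- is.na(out$beta_hat) | out$id == "" | is.na(out$id)
  if (!is.null(se_col)) {
    se <- as.numeric(dt[[se_col]])
    bad <- bad | is.na(se) | se <= 0
    out$s2 <- se^2
  } else {
    badf <- is.na(out$freq) | out$freq < .FREQ_EPS |
      out$freq > 1 - .FREQ_EPS | is.na(out$n) | out$n < 1
    bad <- bad | badf
    out$s2 <- ifelse(badf, NA_real_,
                     1 / (2 * out$n * out$freq * (1 - out$freq)))
  }
  if (any(bad)) {
    log_msg("dropping ", sum(bad), " of ", nrow(out),
            " summary-stat rows with missing or invalid fields")
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0) stop("no usable summary-stat rows in ", path,
                           call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a per-population allele-frequency table
#'
#' Expects columns for variant ID, the counted allele, and its frequency
#' (auto-detected or via `column_map` with names `id`, `allele`, `freq`).
#' Rows with frequencies outside the open unit interval are dropped with a
#' logged reason.
#'
#' @inheritParams read_sumstats
#' @return A data.frame with columns `id`, `allele`, `freq`.
#' @export
read_freq_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, data.table = FALSE)
  cols <- names(dt)
  id_col <- resolve_column(cols, "id", column_map)
  al_col <- resolve_column(cols, "allele", column_map)
  fr_col <- resolve_column(cols, "freq", column_map)
  out <- data.frame(id = as.character(dt[[id_col]]),
                    allele = toupper(as.character(dt[[al_col]])),
                    freq = as.numeric(dt[[fr_col]]),
                    stringsAsFactors = FALSE)
  bad <- is.na(out$freq) | out$freq < .FREQ_EPS | out$freq > 1 - .FREQ_EPS
  if (any(bad)) {
    log_msg("dropping ", sum(bad), " of ", nrow(out),
            " frequency rows outside (0, 1)")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize summary statistics with two allele-frequency tables
#'
#' Joins the three inputs on variant ID (sorted intersection) and aligns
#' everything to the allele coding of the population-1 frequency table.
#' A summary-stat row whose effect allele is the *other* allele relative to
#' that coding has its effect negated and its training frequency
#' complemented (`sign_flipped`); a population-2 frequency recorded for the
#' opposite allele is complemented. Strand-ambiguous variants (A/T, C/G) and
#' variants whose allele sets do not match are dropped; every SNP carries a
#' provenance flag.
#'
#' @param sumstats Data frame from [read_sumstats()].
#' @param freq1,freq2 Data frames from [read_freq_table()] for populations 1
#'   and 2.
#' @return An object of class `harmonized_dataset`: a list with `data` (a
#'   data.frame of retained SNPs: `id`, `effect_allele`, `other_allele`,
#'   `beta_hat`, `s2`, `f`, `g`, `status`), `dropped` (a data.frame of
#'   dropped IDs and reasons), and accessors via [as_summary_stats()] /
#'   [as_panel()].
#' @export
harmonize <- function(sumstats, freq1, freq2) {
  ids <- sort(intersect(intersect(sumstats$id, freq1$id), freq2$id))
  if (length(ids) == 0) {
    stop("no variants shared by summary statistics and both frequency tables",
         call. = FALSE)
  }
  ss <- sumstats[match(ids, sumstats$id), , drop = FALSE]
  p1 <- freq1[match(ids, freq1$id), , drop = FALSE]
  p2 <- freq2[match(ids, freq2$id), , drop = FALSE]

  ea <- ss$effect_allele
  oa <- ss$other_allele
  status <- rep("kept", length(ids))
  beta <- ss$beta_hat
  freq_tr <- if ("freq" %in% names(ss)) ss$freq else rep(NA_real_, length(ids))

  ambiguous <- is_strand_ambiguous(ea, oa)
  status[ambiguous] <- "dropped:strand_ambiguous"

  # Align the sumstats coding to population 1's counted allele.
  match_ea <- p1$allele == ea
  match_oa <- p1$allele == oa
  flip <- !ambiguous & match_oa
  mismatch <- !ambiguous & !match_ea & !match_oa
  status[mismatch] <- "dropped:allele_mismatch"
  if (any(flip)) {
    beta[flip] <- -beta[flip]
    freq_tr[flip] <- 1 - freq_tr[flip]
    tmp <- ea[flip]; ea[flip] <- oa[flip]; oa[flip] <- tmp
    status[flip] <- "sign_flipped"
  }

  # Population 2 frequencies onto the same coding.
  g <- p2$freq
  g_other <- !ambiguous & p2$allele != ea
  g_valid <- p2$allele == ea | p2$allele == oa
  status[!ambiguous & !g_valid & status %in% c("kept", "sign_flipped")] <-
    "dropped:allele_mismatch"
  g[g_other & g_valid] <- 1 - g[g_other & g_valid]

  keep <- status %in% c("kept", "sign_flipped")
  dropped <- data.frame(id = ids[!keep], reason = status[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(dropped) > 0) {
    log_msg("harmonization dropped ", nrow(dropped), " of ", length(ids),
            " shared variants (",
            paste(names(table(dropped$reason)), table(dropped$reason),
                  sep = ": ", collapse = ", "), ")")
  }
  data <- data.frame(id = ids, effect_allele = ea, other_allele = oa,
                     beta_hat = beta, s2 = ss$s2, f = p1$freq, g = g,
                     freq_training = freq_tr, status = status,
                     stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (nrow(data) == 0) {
    stop("harmonization retained no variants", call. = FALSE)
  }
  rownames(data) <- NULL
  structure(list(data = data, dropped = dropped),
            class = "harmonized_dataset")
}

#' @export
print.harmonized_dataset <- function(x, ...) {
  cat("Harmonized dataset:", nrow(x$data), "variants retained,",
      nrow(x$dropped), "dropped\n")
  invisible(x)
}

#' Extract aligned summary statistics from a harmonized dataset
#' @param x A `harmonized_dataset`.
#' @return A [summary_stats()].
#' @export
as_summary_stats <- function(x) {
  stopifnot(inherits(x, "harmonized_dataset"))
  out <- summary_stats(beta_hat = x$data$beta_hat, s2 = x$data$s2,
                       id = x$data$id)
  if (!all(is.na(x$data$freq_training))) out$freq <- x$data$freq_training
  out
}

#' Extract the two-population frequency panel from a harmonized dataset
#' @param x A `harmonized_dataset`.
#' @return A [population_panel()].
#' @export
as_panel <- function(x) {
  stopifnot(inherits(x, "harmonized_dataset"))
  population_panel(f = x$data$f, g = x$data$g, id = x$data$id)
}

#' Read a posterior-sample matrix from tab-separated text
#'
#' Rows are SNPs with the variant ID in the first column; remaining columns
#' are posterior effect draws (e.g. exported from an LDpred2-auto chain).
#'
#' @param path File path.
#' @return A numeric matrix with variant IDs as row names.
#' @export
read_posterior_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, data.table = FALSE)
  if (ncol(dt) < 3) {
    stop("posterior-sample file needs an ID column plus at least 2 sample ",
         "columns", call. = FALSE)
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(dt[[1]])
  m
}

provenance_header <- function(seed = NULL, params = list()) {
  bits <- c(paste0("pgsdiff ", as.character(utils::packageVersion("pgsdiff"))),
            if (!is.null(seed)) paste0("seed=", seed),
            if (length(params)) paste(names(params), unlist(params),
                                      sep = "=", collapse = " "))
  paste0("# ", paste(bits, collapse = " | "))
}

#' Write a risk-difference result as a single-row TSV
#'
#' @param result A `risk_difference` from [summarize_risk_difference()].
#' @param path Output path.
#' @param seed,params Optional provenance recorded in a header comment line.
#' @return `path`, invisibly.
#' @export
write_risk_difference <- function(result, path, seed = NULL, params = list()) {
  stopifnot(inherits(result, "risk_difference"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, params), con)
  writeLines("d_hat\tsd\trr\tci_low\tci_high", con)
  writeLines(paste(format(c(result$d_hat, sqrt(result$d_var), result$rr,
                            result$ci_low, result$ci_high), digits = 10),
                   collapse = "\t"), con)
  invisible(path)
}

#' Write a test result as a single-row TSV
#'
#' @param test A `pgs_test` from [wald_test()] or [t_test_comparator()].
#' @param path Output path.
#' @param seed,params Optional provenance recorded in a header comment line.
#' @return `path`, invisibly.
#' @export
write_test_result <- function(test, path, seed = NULL, params = list()) {
  stopifnot(inherits(test, "pgs_test"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, params), con)
  writeLines("method\tstatistic\tdf\tp_value\tnull_variance", con)
  writeLines(paste(test$method,
                   format(test$statistic, digits = 10), format(test$df),
                   format(test$p_value, digits = 10),
                   format(test$null_variance, digits = 10), sep = "\t"), con)
  invisible(path)
}

#' Write an experiment result table as long-format TSV
#'
#' One row per grid cell per metric, suitable for plotting.
#'
#' @param result Data frame from [run_sd_experiment()] or
#'   [run_frequentist_experiment()].
#' @param path Output path.
#' @param seed,params Optional provenance recorded in a header comment line.
#' @return `path`, invisibly.
#' @export
write_experiment_result <- function(result, path, seed = NULL,
                                    params = list()) {
  stopifnot(is.data.frame(result))
  param_cols <- intersect(c("h2", "p_causal", "fst", "n_eff", "rr", "n_reps"),
                          names(result))
  metric_cols <- setdiff(names(result), param_cols)
  long <- do.call(rbind, lapply(metric_cols, function(mc) {
    data.frame(result[param_cols], metric = mc, value = result[[mc]],
               stringsAsFactors = FALSE)
  }))
  writeLines(provenance_header(seed, params), path)
  data.table::fwrite(long, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}
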