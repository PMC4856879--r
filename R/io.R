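#' Write / read a per-cohort summary-statistic table
#'
#' Whitespace-delimited text with the header columns MARKER, EA, NEA, EAF,
#' BETA, SE, N, P -- the dialect consumed by inverse-variance meta-analysis
#' tools. Markers are written as `snp_<variant>`, the effect allele is the
#' simulated allele 1 (`B`) and the other allele `A`. Floats round-trip at 17
#' significant digits.
#'
#' @param stats a tibble from [single_snp_association()].
#' @param path output file.
#' @return `path`, invisibly (writer); a tibble with the columns of
#'   [single_snp_association()] plus `ea`/`nea` (reader).
#' @export
write_cohort_stats <- function(stats, path) {
  out <- tibble::tibble(MARKER = marker_id(stats$variant),
                        EA = "B", NEA = "A",
                        EAF = fmt_num(stats$eaf),
                        BETA = fmt_num(stats$beta_hat),
                        SE = fmt_num(stats$se),
                        N = stats$n,
                        P = fmt_num(stats$p_value))
  readr::write_delim(out, path, delim = " ")
  invisible(path)
}

#' @rdname write_cohort_stats
#' @export
read_cohort_stats <- function(path) {
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, colClasses = c(
      MARKER = "character", EA = "character", NEA = "character",
      EAF = "numeric", BETA = "numeric", SE = "numeric", N = "numeric",
      P = "numeric")),
    error = function(e) stop("cannot parse cohort table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("MARKER", "EA", "NEA", "EAF", "BETA", "SE", "N", "P")
  if (!all(need %in% names(raw))) {
    stop("cohort table '", path, "' lacks columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  # flip to the canonical orientation (effect allele B)
  flip <- raw$EA == "A" & raw$NEA == "B"
  beta <- ifelse(flip, -raw$BETA, raw$BETA)
  eaf <- ifelse(flip, 1 - raw$EAF, raw$EAF)
  tibble::tibble(variant = marker_index(raw$MARKER),
                 beta_hat = beta, var = raw$SE^2, se = raw$SE,
                 p_value = raw$P, eaf = eaf, n = raw$N,
                 ea = "B", nea = "A")
}

marker_id <- function(variant) paste0("snp_", variant)
marker_index <- function(marker) {
  idx <- suppressWarnings(as.integer(sub("^snp_", "", marker)))
  if (anyNA(idx)) stop("unparseable marker id(s), expected snp_<k>", call. = FALSE)
  idx
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a meta-analysis table
#'
#' Tab-separated with columns MARKER, BETA, SE, P, Q, TAU2, K and DIRECTIONS
#' (one `+`/`-`/`?` per cohort: sign of the cohort's effect, `?` when the
#' cohort did not observe the variant).
#'
#' @param meta an `fm_meta` tibble.
#' @param stats the per-cohort tables the meta was computed from (for the
#'   DIRECTIONS string); optional.
#' @param path file path.
#' @return `path` invisibly (writer); an `fm_meta` tibble (reader).
#' @export
write_meta_table <- function(meta, path, stats = NULL) {
  dir_str <- rep("?", nrow(meta))
  if (!is.null(stats)) {
    dirs <- vapply(seq_len(nrow(meta)), function(i) {
      paste(vapply(stats, function(s) {
        j <- match(meta$variant[i], s$variant)
        if (is.na(j)) "?" else if (s$beta_hat[j] >= 0) "+" else "-"
      }, character(1)), collapse = "")
    }, character(1))
    dir_str <- dirs
  }
  out <- tibble::tibble(MARKER = marker_id(meta$variant),
                        BETA = fmt_num(meta$pooled_beta),
                        SE = fmt_num(meta$se),
                        P = fmt_num(meta$p_value),
                        LOG_P = fmt_num(meta$log_p),
                        Q = fmt_num(meta$q_stat),
                        TAU2 = fmt_num(meta$tau2),
                        K = meta$k,
                        DIRECTIONS = dir_str)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_meta_table
#' @export
read_meta_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    MARKER = "c", BETA = "d", SE = "d", P = "d", LOG_P = "d", Q = "d",
    TAU2 = "d", K = "i", DIRECTIONS = "c"))
  out <- tibble::tibble(variant = marker_index(raw$MARKER),
                        pooled_beta = raw$BETA, pooled_var = raw$SE^2,
                        se = raw$SE, p_value = raw$P, q_stat = raw$Q,
                        tau2 = raw$TAU2, k = raw$K, log_p = raw$LOG_P)
  class(out) <- c("fm_meta", class(out))
  out
}

#' Export a panel in IMPUTE hap/legend format
#'
#' Writes, per population, `<label>.legend` (columns id, position, allele0,
#' allele1) and `<label>.hap` (one row per variant, one space-separated 0/1
#' column per haplotype).
#'
#' @param panel an `fm_panel`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_hap_legend <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  legend <- data.frame(id = marker_id(seq_along(panel$positions)),
                       position = panel$positions,
                       allele0 = "A", allele1 = "B")
  for (pop in names(panel$haplotypes)) {
    readr::write_delim(legend, file.path(dir, paste0(pop, ".legend")), delim = " ")
    h <- t(panel$haplotypes[[pop]]) # rows = variants
    utils::write.table(h, file.path(dir, paste0(pop, ".hap")),
                       row.names = FALSE, col.names = FALSE, sep = " ")
  }
  invisible(dir)
}

#' Read one population's IMPUTE hap/legend pair
#'
#' @param dir directory written by [write_hap_legend()].
#' @param pop population label.
#' @return a list with `legend` (tibble) and `haplotypes` (n_hap x n_variant
#'   0/1 matrix).
#' @export
read_hap_legend <- function(dir, pop) {
  legend <- readr::read_table(file.path(dir, paste0(pop, ".legend")),
                              col_types = readr::cols(
                                id = "c", position = "i", allele0 = "c",
                                allele1 = "c"))
  h <- as.matrix(utils::read.table(file.path(dir, paste0(pop, ".hap"))))
  dimnames(h) <- NULL
  list(legend = legend, haplotypes = t(h))
}

#' Write per-replicate credible-set records
#'
#' Tab-separated per-replicate fine-mapping records: region, replicate,
#' constructed, lead_p, set_size, contains_causal.
#'
#' @param results a data frame with a `region` column plus the per-replicate
#'   columns of [run_scenario()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_credible_set_records <- function(results, path) {
  cols <- c("region", "replicate", "constructed", "lead_p", "set_size",
            "contains_causal")
  readr::write_tsv(results[, intersect(cols, names(results))], path)
  invisible(path)
}
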