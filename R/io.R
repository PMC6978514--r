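# Plain-text interchange: TSV spike tables and epoch tables, TSV pattern
# distributions, YAML model files.

#' Write / read a spike table
#'
#' Two-column TSV (`unit_id`, `spike_time_s`); unit ids are the 1-based
#' positions in the set. The duration and group are carried in `#`-comment
#' header lines.
#'
#' @param s a [spike_train_set].
#' @param path file path.
#' @return `write_spike_trains` returns `path` invisibly;
#'   `read_spike_trains` returns a [spike_train_set].
#' @export
write_spike_trains <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_s\t%.10g", s$duration), con)
  writeLines(sprintf("# group\t%s", s$group), con)
  df <- data.frame(
    unit_id = rep(seq_along(s$spike_times),
                  vapply(s$spike_times, length, integer(1))),
    spike_time_s = unlist(s$spike_times, use.names = FALSE))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  hdr <- readLines(path, n = 2)
  duration <- as.numeric(sub("# duration_s\t", "", hdr[1], fixed = TRUE))
  group <- sub("# group\t", "", hdr[2], fixed = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  n <- if (nrow(df)) max(df$unit_id) else 0
  st <- lapply(seq_len(n), function(u) df$spike_time_s[df$unit_id == u])
  spike_train_set(st, duration, group)
}

#' Write / read an epoch table
#'
#' Three-column TSV (`start_s`, `end_s`, `label`), BED-like.
#'
#' @param e an [epoch_set].
#' @param path file path.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` an
#'   [epoch_set].
#' @export
write_epochs <- function(e, path) {
  utils::write.table(
    data.frame(start_s = e$start, end_s = e$end, label = e$label),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  epoch_set(df$start_s, df$end_s, df$label)
}

#' Write / read a pattern distribution
#'
#' TSV of `pattern_index` (0-based; unit 1 = least-significant bit) and
#' `probability`; only patterns with positive probability are written.
#'
#' @param d a `pattern_distribution`.
#' @param path file path.
#' @return `write_pattern_distribution` returns `path` invisibly;
#'   `read_pattern_distribution` a `pattern_distribution`.
#' @export
write_pattern_distribution <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N\t%d", d$N), con)
  writeLines(sprintf("# n_samples\t%.10g", d$n_samples), con)
  idx <- which(d$p > 0)
  utils::write.table(
    data.frame(pattern_index = idx - 1L, probability = d$p[idx]),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pattern_distribution
#' @export
read_pattern_distribution <- function(path) {
  hdr <- readLines(path, n = 2)
  N <- as.integer(sub("# N\t", "", hdr[1], fixed = TRUE))
  n_samples <- as.numeric(sub("# n_samples\t", "", hdr[2], fixed = TRUE))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  p <- numeric(2^N)
  p[df$pattern_index + 1L] <- df$probability
  pattern_distribution(p / sum(p), n_samples)
}

#' Write / read a maximum-entropy model as YAML
#'
#' Serialises `N`, `order`, `h`, `J` and `logZ`. The coupling convention is
#' recorded in the file: the exponent is
#' `sum_i h_i sigma_i + 1/2 sum_{i != j} J_ij sigma_i sigma_j`.
#'
#' @param m a [maxent_model].
#' @param path file path.
#' @return `write_maxent_model` returns `path` invisibly;
#'   `read_maxent_model` a [maxent_model].
#' @export
write_maxent_model <- function(m, path) {
  yaml::write_yaml(list(
    convention = "P(sigma) = exp(sum_i h_i sigma_i + 0.5 sum_{i!=j} J_ij sigma_i sigma_j) / Z",
    N = m$N, order = m$order, h = as.numeric(m$h),
    J = lapply(seq_len(m$N), function(i) as.numeric(m$J[i, ])),
    logZ = m$logZ), path, precision = 15)
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  y <- yaml::read_yaml(path)
  J <- do.call(rbind, lapply(y$J, as.numeric))
  maxent_model(as.numeric(y$h), J)
}
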