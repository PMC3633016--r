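#' Read a benchmark-suite configuration file
#'
#' Flat `key = value` format, `#` comments allowed. Keys: `patterns` and
#' `targets` (comma-separated file paths or glob patterns), `variants`
#' (`ri`, `ri-ds`), `modes` (`monomorphism`, `induced`), `directed`
#' (`true`/`false`, default false), `edge_labels` (default false), `timeout`
#' (seconds, default 180).
#'
#' @param path Config file path.
#' @return A config list accepted by [run_suite()].
#' @export
read_suite_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[trimws(lines) != ""])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  conf <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
  splitv <- function(x) trimws(strsplit(x, ",")[[1L]])
  expand <- function(specs) unlist(lapply(specs, function(s)
    if (grepl("[*?]", s)) Sys.glob(s) else s))
  list(
    patterns = expand(splitv(conf$patterns %||% "")),
    targets = expand(splitv(conf$targets %||% "")),
    variants = splitv(conf$variants %||% "ri"),
    modes = splitv(conf$modes %||% "monomorphism"),
    directed = tolower(conf$directed %||% "false") %in% c("true", "1", "yes"),
    edge_labels = tolower(conf$edge_labels %||% "false") %in% c("true", "1", "yes"),
    timeout = as.numeric(conf$timeout %||% "180"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a pattern-by-target benchmark suite
#'
#' Executes the full Cartesian product of patterns x targets x variants x
#' modes, one matcher run each, and collects per-run search statistics. For
#' the plain variant the reported `seconds` cover search only; for the
#' initial-domain variant they include domain preprocessing, since that is
#' part of its matching cost. Aggregate means and standard deviations per
#' (variant, mode) group exclude timed-out runs; a group with only timeouts
#' reports `NA`, never zero.
#'
#' @param config A config list (see [read_suite_config()]) or a path to a
#'   config file. Pattern/target entries may be file paths or
#'   [labeled_graph()] objects.
#' @param output Optional CSV path; runs are written one per row, followed by
#'   `#`-prefixed aggregate lines (readable back with `readr::read_csv(...,
#'   comment = "#")`).
#' @return Tibble of runs with columns `pattern`, `target`, `variant`, `mode`,
#'   `visited`, `matches`, `seconds`, `timed_out`, and the aggregate tibble as
#'   attribute `"summary"` (also via [suite_summary()]).
#' @export
run_suite <- function(config, output = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_suite_config(config)
  load_g <- function(x) {
    if (inherits(x, "labeled_graph")) return(x)
    if (!file.exists(x)) stop("missing graph file: ", x)
    read_graph(x, directed = isTRUE(config$directed))
  }
  for (f in c(config$patterns, config$targets))
    if (is.character(f) && !file.exists(f)) stop("missing graph file: ", f)
  pats <- lapply(config$patterns, load_g)
  tgts <- lapply(config$targets, load_g)
  if (!length(pats) || !length(tgts)) stop("config must list patterns and targets")
  gname <- function(x, i) if (inherits(x, "labeled_graph")) x$name else basename(x)

  grid <- expand.grid(pi = seq_along(pats), ti = seq_along(tgts),
                      variant = config$variants, mode = config$modes,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    p <- pats[[grid$pi[k]]]; tg <- tgts[[grid$ti[k]]]
    variant <- grid$variant[k]; mode <- grid$mode[k]
    t0 <- proc.time()[["elapsed"]]
    dom <- if (variant == "ri-ds") ri_domains(p, tg)
    res <- count_matches(p, tg, mode = match_mode(mode, config$edge_labels %||% FALSE),
                         domains = dom, timeout = config$timeout %||% 180)
    secs <- proc.time()[["elapsed"]] - t0   # includes preprocessing for ri-ds
    rows[[k]] <- tibble::tibble(
      pattern = gname(config$patterns[[grid$pi[k]]]),
      target = gname(config$targets[[grid$ti[k]]]),
      variant = variant, mode = mode,
      visited = res$stats$visited_nodes, matches = res$count,
      seconds = if (variant == "ri-ds") secs else res$stats$elapsed,
      timed_out = res$stats$timed_out)
  }
  runs <- dplyr::bind_rows(rows)
  summ <- suite_summary(runs)
  attr(runs, "summary") <- summ
  class(runs) <- c("ri_suite", class(runs))
  if (!is.null(output)) {
    readr::write_csv(runs, output)
    lines <- c("# aggregate (timed-out runs excluded from means)",
               paste0("# ", paste(colnames(summ), collapse = ",")),
               paste0("# ", apply(summ, 1L, function(r)
                 paste(ifelse(is.na(r), "", trimws(format(r, digits = 6))),
                       collapse = ","))))
    cat(lines, file = output, sep = "\n", append = TRUE)
  }
  runs
}

#' Aggregate suite runs per (variant, mode) group
#'
#' @param runs Tibble from [run_suite()].
#' @return Tibble with per-group means and standard deviations of seconds,
#'   visited nodes and match counts, computed over completed runs only; `NA`
#'   when every run in a group timed out.
#' @export
suite_summary <- function(runs) {
  runs |>
    dplyr::group_by(.data$variant, .data$mode) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      n_timeouts = sum(.data$timed_out),
      mean_seconds = mean(.data$seconds[!.data$timed_out]),
      sd_seconds = stats::sd(.data$seconds[!.data$timed_out]),
      mean_visited = mean(.data$visited[!.data$timed_out]),
      sd_visited = stats::sd(.data$visited[!.data$timed_out]),
      mean_matches = mean(.data$matches[!.data$timed_out]),
      sd_matches = stats::sd(.data$matches[!.data$timed_out]),
      .groups = "drop")
}

#' Plot suite search effort by variant and mode
#'
#' @param object Tibble of runs from [run_suite()].
#' @param ... Unused.
#' @return A ggplot: visited search-tree nodes (log scale) per variant,
#'   faceted by match mode; timed-out runs are marked.
#' @method autoplot ri_suite
#' @export
autoplot.ri_suite <- function(object, ...) autoplot_suite(object, ...)

#' @rdname autoplot.ri_suite
#' @param runs Tibble of runs from [run_suite()].
#' @export
autoplot_suite <- function(runs, ...) {
  ggplot2::ggplot(runs, ggplot2::aes(x = .data$variant, y = .data$visited)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$timed_out),
                         width = 0.15, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = NULL, y = "visited search-tree nodes",
                  colour = "timed out") +
    ggplot2::theme_minimal()
}
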