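# Internal helpers: condition classes, TSV dialect, RNG scoping.

dn_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "dn_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

dn_input_error  <- function(msg, ...) dn_stop("dn_input_error", msg, ...)
dn_config_error <- function(msg, ...) dn_stop("dn_config_error", msg, ...)
dn_usage_error  <- function(msg, ...) dn_stop("dn_usage_error", msg, ...)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# TSV dialect: tab-separated, UTF-8, '.' decimal, no quoting, '#' comments.
dn_read_tsv <- function(path, ...) {
  if (!file.exists(path)) dn_input_error("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    quote = "", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

dn_write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

dn_provenance <- function(seed = NULL, ...) {
  extra <- list(...)
  parts <- c(
    sprintf("droughtnet %s",
            as.character(utils::packageVersion("droughtnet"))),
    sprintf("date=%s", format(Sys.time(), "%Y-%m-%d")),
    if (!is.null(seed)) sprintf("seed=%s", seed),
    if (length(extra)) paste(names(extra), unlist(extra), sep = "=")
  )
  paste(parts, collapse = " ")
}

# Evaluate `expr` under a local RNG stream; the caller's RNG state is
# untouched. Keeps independent ops reproducible from one config seed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}
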