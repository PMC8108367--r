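# Internal helpers shared across modules: classified error conditions
# (so the CLI can map them to exit codes) and seeded-RNG scoping.

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("spotdecon_input_error", "spotdecon_error")))
}

stop_numeric <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("spotdecon_numeric_error", "spotdecon_error")))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Numbers are always written with the C-locale "%.10g" so that files
# round-trip to >= 6 significant digits and identical runs are
# byte-identical.
format_num <- function(x) sprintf("%.10g", x)

assert_expression_matrix <- function(values, what = "expression matrix") {
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("%s must be a numeric matrix", what)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_input("%s must carry gene (row) and sample (column) identifiers", what)
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop_input("duplicate gene identifiers in %s: %s", what,
               paste(utils::head(dup_g, 5L), collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop_input("duplicate sample identifiers in %s: %s", what,
               paste(utils::head(dup_s, 5L), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop_input("%s contains missing or non-finite values", what)
  if (any(values < 0))
    stop_input("%s contains negative entries", what)
  invisible(values)
}

assert_labels <- function(labels, sample_ids = NULL) {
  if (!is.data.frame(labels) || !all(c("sample_id", "label") %in% names(labels)))
    stop_input("labels must be a data.frame with columns 'sample_id' and 'label'")
  if (anyDuplicated(labels$sample_id))
    stop_input("labels contain duplicated sample ids")
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, labels$sample_id)
    if (length(miss))
      stop_input("labels missing for %d sample(s), e.g. %s", length(miss),
                 paste(utils::head(miss, 5L), collapse = ", "))
  }
  invisible(labels)
}

assert_coordinates <- function(coords) {
  if (!is.data.frame(coords) || !all(c("sample_id", "x", "y") %in% names(coords)))
    stop_input("coordinates must be a data.frame with columns 'sample_id', 'x', 'y'")
  if (anyDuplicated(coords$sample_id))
    stop_input("coordinate table has duplicated sample ids")
  if (anyNA(coords$x) || anyNA(coords$y) ||
      any(!is.finite(coords$x)) || any(!is.finite(coords$y)))
    stop_input("coordinates must be finite")
  invisible(coords)
}
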