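# shared validation / selection helpers (internal)

stop_engram <- function(fmt, ..., class = "engramtx_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Resolve a cell selector against a GeneExpressionTable (or a vector of ids).
# Accepts: logical vector (length n_cells), integer indices, character cell_ids,
# or a one-argument function of cell_meta returning a logical vector.
resolve_cells <- function(table, selector, what = "selector") {
  ids <- table$cell_meta$cell_id
  n <- length(ids)
  if (is.function(selector)) {
    selector <- selector(table$cell_meta)
  }
  if (is.logical(selector)) {
    if (length(selector) != n) {
      stop_engram("%s: logical selector has length %d, expected %d cells",
                  what, length(selector), n)
    }
    idx <- which(selector)
  } else if (is.numeric(selector)) {
    idx <- as.integer(selector)
    if (any(idx < 1L | idx > n)) {
      stop_engram("%s: cell index out of range 1..%d", what, n)
    }
  } else if (is.character(selector)) {
    idx <- match(selector, ids)
    if (anyNA(idx)) {
      stop_engram("%s: unknown cell ids: %s", what,
                  paste(selector[is.na(idx)][seq_len(min(5, sum(is.na(idx))))],
                        collapse = ", "))
    }
  } else {
    stop_engram("%s: unsupported selector type '%s'", what, class(selector)[1])
  }
  if (length(idx) == 0L) stop_engram("%s selects no cells", what)
  idx
}

# dense numeric matrix from a (possibly sparse) genes x cells slice
dense_slice <- function(mat, cols) {
  as.matrix(mat[, cols, drop = FALSE])
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_engram("%s must be a single fraction in [0, 1]", name)
  }
  x
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop_engram("%s must be a single nonnegative number", name)
  }
  x
}
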