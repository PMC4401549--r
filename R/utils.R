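# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce outcome labels to 0/1: accepts logical, 0/1 numeric, or a factor/character
# with exactly two levels (the *higher* sorted level is treated as the positive class
# unless it matches a known responder code).
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L) stop("labels must have exactly two classes, got: ",
                             paste(lv, collapse = ", "))
  pos <- if (any(lv %in% c("CR", "CR/CRi", "responder", "yes", "1"))) {
    lv[lv %in% c("CR", "CR/CRi", "responder", "yes", "1")][1L]
  } else lv[2L]
  as.integer(as.character(labels) == pos)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# scaled Mann-Whitney statistic on two numeric vectors (midrank tie handling):
# P(X > Y) + 0.5 * P(X == Y) for X drawn from `x`, Y from `y`.
scaled_u <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both samples must be nonempty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  u / (nx * ny)
}

# fast AUROC given positive-class and negative-class score vectors
auroc_fast <- function(pos, neg) scaled_u(pos, neg)

has_ties <- function(x, y) anyDuplicated(c(x, y)) > 0L
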