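# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
.check_groups <- function(groups, samples) {
  if (is.null(names(groups))) {
    if (length(groups) != length(samples))
      .stopf("group vector has %d entries for %d samples",
             length(groups), length(samples))
    names(groups) <- samples
  }
  missing <- setdiff(samples, names(groups))
  if (length(missing))
    .stopf("no group label for sample(s): %s", paste(missing, collapse = ", "))
  g <- setNames(as.character(groups[samples]), samples)
  lv <- unique(g)
  if (length(lv) != 2L)
    .stopf("exactly two groups required, found: %s", paste(lv, collapse = ", "))
  g
}

# Orders the two group labels as (control, case). Recognizes common control
# spellings; otherwise the first label in sorted order is the control.
.group_levels <- function(g, control = NULL) {
  lv <- sort(unique(g))
  if (!is.null(control)) {
    if (!control %in% lv) .stopf("control group '%s' not present", control)
    return(c(control, setdiff(lv, control)))
  }
  ctrl_like <- lv[tolower(lv) %in% c("control", "ctrl", "normal", "healthy")]
  if (length(ctrl_like) == 1L) c(ctrl_like, setdiff(lv, ctrl_like)) else lv
}

# Welch two-tailed t-test with explicit degenerate conventions:
# both groups (near-)constant and equal means -> p = 1; constant but unequal
# means -> smallest representable double, flagged. Returns list(p, flag).
.welch_p <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    return(list(p = NA_real_, flag = "too_few"))
  vx <- var(x); vy <- var(y)
  eps <- .Machine$double.eps * max(1, abs(mean(x)), abs(mean(y)))^2 * 100
  if (vx <= eps && vy <= eps) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(p = 1, flag = "degenerate_equal"))
    return(list(p = .Machine$double.xmin, flag = "degenerate_unequal"))
  }
  p <- tryCatch(t.test(x, y, var.equal = FALSE)$p.value,
                error = function(e) NA_real_)
  if (is.na(p)) {
    # t.test refuses when the pooled data are essentially constant
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(p = 1, flag = "degenerate_equal"))
    return(list(p = .Machine$double.xmin, flag = "degenerate_unequal"))
  }
  list(p = p, flag = "ok")
}

# derive a reproducible child seed (< 2^31) from a base seed and a tag
.child_seed <- function(seed, tag) {
  (as.integer(seed) %% 1000003L) * 1009L + sum(utf8ToInt(tag)) %% 1009L
}
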