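# internal helpers shared across modules

match_axis <- function(axis) {
  match.arg(axis, c("rows", "columns"))
}

# stable descending order: ties keep original position
order_desc_stable <- function(x) {
  order(-x, seq_along(x))
}

# row/col moments that ignore missing entries; ddof as in sample statistics
vec_mean <- function(v) mean(v, na.rm = TRUE)

vec_var <- function(v, ddof = 1) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n <= ddof) return(NA_real_)
  sum((v - mean(v))^2) / (n - ddof)
}

axis_vectors <- function(values, axis) {
  if (axis == "rows") values else t(values)
}

cv_abort <- function(..., class = "clustviz_error") {
  stop(errorCondition(paste0(...), class = c(class, "clustviz_error")))
}

cv_log <- function(..., verbose = getOption("clustviz.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
}
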