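# internal helpers shared across modules

#' @keywords internal
#' @noRd
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# deterministic lexicographic tie-break: smallest element of x
#' @noRd
.lexmin <- function(x) sort(as.character(x))[1L]

# quiet per-stage logging; collected with options(paralogon.verbose=TRUE)
#' @noRd
.plog <- function(...) {
  if (isTRUE(getOption("paralogon.verbose", FALSE)))
    message("[paralogon] ", sprintf(...))
  invisible(NULL)
}

# rank within groups, 0-based, by an order key
#' @noRd
.rank0 <- function(key, group) {
  r <- integer(length(key))
  for (g in unique(group)) {
    i <- which(group == g)
    r[i] <- order(order(key[i])) - 1L
  }
  r
}

#' Expression level from FPKM
#'
#' Log-transformed expression with a small offset so that unexpressed genes
#' (FPKM = 0) remain finite: \code{log10(fpkm + 0.1)}.
#'
#' @param fpkm numeric vector of FPKM values (>= 0).
#' @param base logarithm base, default 10.
#' @return numeric vector of expression levels.
#' @export
#' @examples
#' expressionLevel(c(0, 0.9, 99.9))
expressionLevel <- function(fpkm, base = 10) {
  .assert(all(fpkm >= 0, na.rm = TRUE), "fpkm must be non-negative")
  log(fpkm + 0.1, base = base)
}
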