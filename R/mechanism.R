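# Algorithmic generation of the degradation mechanism from the carbon count:
# a cascade of halving breakage steps over fictitious lumped fragments,
# closed by a terminal mineralization step that removes carbon from the
# organic (TOC) pool.

#' Build the fragmentation chain of a compound
#'
#' For a carbon count `nc >= 2` the chain halves the fictitious carbon number
#' at each breakage step, `FNC_b = nc / 2^b`, and the number of fragments `F`
#' is the smallest integer with `2^F >= nc` (so `F = ceiling(log2(nc))`).
#' Each breakage step produces two product fragments. For `nc = 1` a single
#' intermediate with one carbon is produced with 1:1 stoichiometry.
#'
#' @param nc Integer carbon count, `>= 1`.
#' @return Object of class `fragment_chain` with fields `fncs` (fictitious
#'   carbon numbers, index 0..F; entry 1 is the target itself),
#'   `n_fragments` and `doubling` (per-step product multiplicity).
#' @examples
#' fragment_chain(8)$fncs   # 8 4 2 1
#' fragment_chain(14)$fncs  # 14 7 3.5 1.75 0.875
#' @export
fragment_chain <- function(nc) {
  if (length(nc) != 1L || !is.numeric(nc) || is.na(nc) ||
      nc < 1 || nc != round(nc))
    stop("invalid compound: carbon count must be a positive integer")
  nc <- as.numeric(nc)
  if (nc == 1) {
    fncs <- c(1, 1); doubling <- 1
  } else {
    F_ <- ceiling(log2(nc))
    fncs <- nc / 2^(0:F_); doubling <- 2
  }
  structure(list(fncs = fncs, n_fragments = length(fncs) - 1L,
                 doubling = doubling, nc = nc),
            class = "fragment_chain")
}

#' Generate the degradation mechanism of a target compound
#'
#' The mechanism is a list of second-order reactions of the organic species
#' with the hydroxyl radical: the first attack on the target (rate constant
#' role `"target"`), one breakage step per fragment (role `"fragment"`), and
#' a final terminal step that mineralizes the last fragment, removing its
#' carbon from the TOC pool. Total reaction count is `F + 1`.
#'
#' @param compound A [target_compound()].
#' @return Object of class `degradation_mechanism` with fields `chain`
#'   ([fragment_chain()]), `reactions` (data frame: `reactant` index b,
#'   `role`, `product` index or `NA` for mineralization, `multiplicity`) and
#'   `species` (organic species names: `target`, `f1`, ..., `fF`).
#' @examples
#' build_mechanism(fenton_compounds("PCT"))
#' @export
build_mechanism <- function(compound) {
  stopifnot(inherits(compound, "target_compound"))
  chain <- fragment_chain(compound$nc)
  F_ <- chain$n_fragments
  reactions <- data.frame(
    reactant = 0:F_,
    role = c("target", rep("fragment", F_)),
    product = c(seq_len(F_), NA),
    multiplicity = c(rep(chain$doubling, F_), 1),
    stringsAsFactors = FALSE
  )
  structure(list(compound = compound, chain = chain, reactions = reactions,
                 species = c("target", paste0("f", seq_len(F_)))),
            class = "degradation_mechanism")
}

#' @export
print.fragment_chain <- function(x, ...) {
  cat("Fragmentation chain:", paste(signif(x$fncs, 4), collapse = " -> "),
      sprintf("(%d fragments)\n", x$n_fragments))
  invisible(x)
}

#' @export
print.degradation_mechanism <- function(x, ...) {
  cat("Degradation mechanism for", x$compound$name,
      sprintf("(NC = %g)\n", x$chain$nc))
  print(x$chain)
  fn <- x$chain$fncs
  for (i in seq_len(nrow(x$reactions))) {
    r <- x$reactions[i, ]
    lhs <- if (r$reactant == 0) "target" else paste0("f", r$reactant)
    rhs <- if (is.na(r$product)) "mineralized carbon"
           else paste0(r$multiplicity, " f", r$product)
    cat(sprintf("  [%s] %s + HO* -> %s\n", r$role, lhs, rhs))
  }
  cat("  TOC =", paste(sprintf("%g*[%s]", fn, c("target",
      paste0("f", seq_len(x$chain$n_fragments)))), collapse = " + "), "\n")
  invisible(x)
}
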