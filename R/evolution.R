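# Constant-size neutral-evolution model: at each step a random parent is
# copied, a single random bit of the copy is flipped, and the child replaces
# a random member of the population. Variants: the child replaces its own
# parent, or is built by single-point recombination of two parents before
# the mutation.

#' Initial population of identical bit strings
#'
#' N copies of the all-zero string of length B, step counter at zero.
#'
#' @param N Population size (at least 2).
#' @param B String length.
#' @return A `bs_population`: list with `members` (N x B integer matrix) and
#'   `steps`.
#' @export
init_population <- function(N, B) {
  stopifnot(N >= 2, B >= 1)
  structure(list(members = matrix(0L, N, B), steps = 0L), class = "bs_population")
}

#' @export
print.bs_population <- function(x, ...) {
  cat("Neutral-evolution population: N =", nrow(x$members),
      "strings of length B =", ncol(x$members), "after", x$steps, "steps\n")
  invisible(x)
}

#' One step of the neutral-evolution model
#'
#' @param pop A `bs_population`.
#' @param variant `"random-death"` (default): the mutated copy of a random
#'   parent replaces a uniformly chosen member, possibly the parent itself;
#'   `"replace-parent"`: the child replaces its own parent;
#'   `"recombination"`: the child is a single-point crossover of two distinct
#'   random parents, then mutated, and replaces a random member.
#' @param exclude_parent If `TRUE`, the victim draw excludes the parent
#'   (records the ambiguity of "another randomly selected" member; default
#'   `FALSE`, i.e. the parent may die).
#' @return The updated population; size and string length are unchanged.
#' @export
evolve_step <- function(pop,
                        variant = c("random-death", "replace-parent", "recombination"),
                        exclude_parent = FALSE) {
  stopifnot(inherits(pop, "bs_population"))
  variant <- match.arg(variant)
  X <- pop$members
  N <- nrow(X); B <- ncol(X)
  if (variant == "recombination") {
    if (B < 2) stop("recombination needs B >= 2")
    ps <- sample.int(N, 2L)           # two distinct parents
    cut <- sample.int(B - 1L, 1L)     # uniform internal crossover point
    child <- c(X[ps[1L], seq_len(cut)], X[ps[2L], (cut + 1L):B])
    parent <- ps[1L]
  } else {
    parent <- sample.int(N, 1L)
    child <- X[parent, ]
  }
  flip <- sample.int(B, 1L)
  child[flip] <- 1L - child[flip]
  victim <- if (variant == "replace-parent") parent
            else if (exclude_parent) sample(seq_len(N)[-parent], 1L)
            else sample.int(N, 1L)
  X[victim, ] <- child
  pop$members <- X
  pop$steps <- pop$steps + 1L
  pop
}

#' Distribution of pairwise Hamming distances
#'
#' Frequencies f_H over H = 0..B across all N(N-1)/2 unordered pairs of the
#' population (duplicate strings count, so H = 0 can have positive weight).
#'
#' @param x A `bs_population` or a 0/1 matrix with at least two rows.
#' @return Numeric vector of length B + 1, named "0".."B", summing to 1.
#' @export
hamming_frequencies <- function(x) {
  X <- .as_bit_matrix(x)
  N <- nrow(X); B <- ncol(X)
  if (N < 2L) stop("need at least two strings to form pairs")
  D <- hamming_matrix(X)
  d <- D[upper.tri(D)]
  f <- tabulate(d + 1L, nbins = B + 1L) / length(d)
  names(f) <- 0:B
  f
}

#' Hamming-distance distribution of a random bit-string set
#'
#' In an uncorrelated random set, two strings differ at exactly H positions
#' with probability `2^-B * choose(B, H)` - a symmetric binomial over
#' H = 0..B with mode at B/2.
#'
#' @param B String length.
#' @return Numeric vector of length B + 1, named "0".."B".
#' @export
random_reference <- function(B) {
  stopifnot(B >= 1)
  f <- dbinom(0:B, B, 0.5)
  names(f) <- 0:B
  f
}

#' Squared-difference divergence between two distance distributions
#'
#' `sum_H (f[H] - fref[H])^2`; the convergence diagnostic of the
#' neutral-evolution model, measured against [random_reference()].
#'
#' @param f,fref Numeric vectors of equal length (frequencies over H = 0..B).
#' @return Nonnegative scalar; zero iff the histograms coincide.
#' @export
divergence <- function(f, fref) {
  if (length(f) != length(fref))
    stop("histograms have different lengths (", length(f), " vs ", length(fref), ")")
  sum((f - fref)^2)
}

#' Run the neutral-evolution model and record its convergence
#'
#' Evolves a population of N initially identical strings for `total_steps`
#' elementary steps, recording the divergence D(T) between the current
#' pairwise Hamming-distance distribution and the random-set reference at a
#' fixed cadence. Time is also reported rescaled by N*B, the mean waiting
#' time for any single bit in the population to mutate. D(T) first decays
#' exponentially and then fluctuates around a plateau whose level scales as
#' 1/N at fixed B.
#'
#' Random draws are made in blocks internally, so the stream of a
#' `run_evolution()` call differs from stepping [evolve_step()] by hand even
#' under the same seed; each entry point is individually reproducible.
#'
#' @param N,B Population size and string length.
#' @param total_steps Number of elementary steps (at least 1).
#' @param record_every Recording cadence in steps; default `N*B/100`.
#'   Recomputing the O(N^2) histogram dominates the cost, so it is done only
#'   at record points.
#' @param variant,exclude_parent Passed to the step rule; see [evolve_step()].
#' @param seed Optional integer seed applied before the run.
#' @return Data frame with columns `step`, `rescaled_time` (= step/(N*B)) and
#'   `D`, including the initial state at step 0.
#' @seealso [plateau_divergence()] for the late-time plateau estimate.
#' @export
run_evolution <- function(N, B, total_steps,
                          record_every = max(1L, round(N * B / 100)),
                          variant = c("random-death", "replace-parent", "recombination"),
                          exclude_parent = FALSE, seed = NULL) {
  stopifnot(N >= 2, B >= 1, total_steps >= 1, record_every >= 1)
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(0, N, B) # double storage: histogram records go through BLAS
  fref <- dbinom(0:B, B, 0.5)
  npairs <- N * (N - 1) / 2
  rec <- unique(c(seq(0L, total_steps, by = record_every), total_steps))
  Dval <- numeric(length(rec))
  up <- .upper_pairs(N)
  idx <- cbind(up$i, up$j)
  measure <- function() {
    r <- rowSums(X)
    d <- r[up$i] + r[up$j] - 2 * tcrossprod(X)[idx]
    f <- tabulate(d + 1L, nbins = B + 1L) / npairs
    sum((f - fref)^2)
  }
  Dval[1L] <- measure()
  ri <- 2L
  step <- 0L
  chunk <- 10000L
  while (step < total_steps) {
    k <- min(chunk, total_steps - step)
    parents <- sample.int(N, k, replace = TRUE)
    flips <- sample.int(B, k, replace = TRUE)
    victims <- switch(variant,
      "random-death"   = sample.int(N, k, replace = TRUE),
      "replace-parent" = parents,
      "recombination"  = sample.int(N, k, replace = TRUE))
    parents2 <- if (variant == "recombination") sample.int(N, k, replace = TRUE) else NULL
    cuts <- if (variant == "recombination") sample.int(B - 1L, k, replace = TRUE) else NULL
    for (t in seq_len(k)) {
      p <- parents[t]
      if (variant == "recombination") {
        p2 <- parents2[t]
        while (p2 == p) p2 <- sample.int(N, 1L)
        cut <- cuts[t]
        child <- c(X[p, seq_len(cut)], X[p2, (cut + 1L):B])
      } else {
        child <- X[p, ]
      }
      child[flips[t]] <- 1L - child[flips[t]]
      v <- victims[t]
      if (exclude_parent && variant != "replace-parent") {
        while (v == p) v <- sample.int(N, 1L)
      }
      X[v, ] <- child
      step <- step + 1L
      if (ri <= length(rec) && step == rec[ri]) {
        Dval[ri] <- measure()
        ri <- ri + 1L
      }
    }
  }
  out <- data.frame(step = rec, rescaled_time = rec / (N * B), D = Dval)
  attr(out, "N") <- N; attr(out, "B") <- B; attr(out, "variant") <- variant
  out
}

#' Late-time plateau of a divergence trajectory
#'
#' Mean of D over the final fraction of recorded points; used to test the
#' 1/N scaling of the asymptotic divergence level.
#'
#' @param traj Data frame from [run_evolution()] (column `D`) or one
#'   (N, B) slice of an [experiment_divergence()] result (column `D_mean`).
#' @param tail_frac Fraction of the record used, default 0.2.
#' @export
plateau_divergence <- function(traj, tail_frac = 0.2) {
  d <- if (!is.null(traj$D)) traj$D else traj$D_mean
  if (is.null(d)) stop("need a 'D' or 'D_mean' column")
  n <- length(d)
  mean(d[seq.int(max(1L, n - ceiling(n * tail_frac) + 1L), n)])
}
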