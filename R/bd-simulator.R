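#' Simulate a constant-rate birth-death chronogram
#'
#' Event-driven (Gillespie) simulation of the linear birth-death process:
#' with `k` live lineages the waiting time to the next event is
#' exponential with rate `(lambda + mu) * k`, a uniformly chosen lineage
#' then either splits (probability `lambda / (lambda + mu)`) or dies.
#' Extinct subtrees are pruned before output, so the returned tree is the
#' reconstructed chronogram an empiricist would see; it is exactly
#' ultrametric with all extant tips at the present.
#'
#' Conditioning is by rejection, which reproduces the conditional law
#' exactly: the whole realization is resimulated until the condition
#' holds (`survival`: at least one extant tip; `crown_both_survive`:
#' both basal lineages of the crown pair leave extant descendants, the
#' conditioning under which [crown_size_cdf()] describes the clade-size
#' law). True node ages are recorded at generation time from the event
#' clock, independent of any branch-length arithmetic on the output tree.
#'
#' @param lambda speciation rate per lineage per Ma, `> 0`.
#' @param mu extinction rate per lineage per Ma, `0 <= mu < lambda`.
#' @param t_stop simulation duration in Ma (origin or crown to present).
#'   Exactly one of `t_stop` / `n_stop` must be given.
#' @param n_stop stop when this many lineages are alive (pure birth
#'   only, `mu = 0`: with extinction the stopping rule would make the
#'   conditioning ambiguous).
#' @param start_mode `"crown_pair"` (two lineages at time 0, the crown
#'   node) or `"single_lineage"`.
#' @param condition `"none"`, `"survival"`, or `"crown_both_survive"`
#'   (requires `start_mode = "crown_pair"`).
#' @param sampling_fraction if `< 1`, [subsample_tips()] is applied to
#'   the result with this retention probability.
#' @param seed optional integer; if given, `set.seed(seed)` is called so
#'   identical seed + configuration gives an identical result.
#' @param max_attempts rejection-loop guard; exceeded attempts raise an
#'   error reporting the estimated acceptance probability.
#' @return An object of class `"bd_sim"`: list with `tree` (a
#'   `c("chronogram", "phylo")` tree, or `NULL` when fewer than 2 tips
#'   survive — see `degenerate`), `node_ages` (true ages in Ma of the
#'   tree's internal nodes, named by node number), `n_extant`,
#'   `degenerate`, `attempts`, `lineages` (the raw genealogy table) and
#'   `config`.
#' @examples
#' sim <- simulate_bd(lambda = 1, mu = 0, t_stop = 2,
#'                    condition = "crown_both_survive", seed = 1)
#' sim$n_extant
#' @export
simulate_bd <- function(lambda, mu = 0, t_stop = NULL, n_stop = NULL,
                        start_mode = c("crown_pair", "single_lineage"),
                        condition = c("none", "survival", "crown_both_survive"),
                        sampling_fraction = 1, seed = NULL,
                        max_attempts = 1e6) {
  start_mode <- match.arg(start_mode)
  condition <- match.arg(condition)
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (mu < 0 || mu >= lambda)
    stop("mu must satisfy 0 <= mu < lambda (r = lambda - mu > 0)", call. = FALSE)
  if (is.null(t_stop) == is.null(n_stop))
    stop("exactly one of t_stop / n_stop must be set", call. = FALSE)
  if (!is.null(n_stop) && mu > 0)
    stop("n_stop is only supported for pure birth (mu = 0)", call. = FALSE)
  if (!is.null(t_stop) && t_stop <= 0) stop("t_stop must be > 0", call. = FALSE)
  if (condition == "crown_both_survive" && start_mode != "crown_pair")
    stop("condition 'crown_both_survive' requires start_mode 'crown_pair'",
         call. = FALSE)
  if (sampling_fraction <= 0 || sampling_fraction > 1)
    stop("sampling_fraction must be in (0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  config <- list(lambda = lambda, mu = mu, t_stop = t_stop, n_stop = n_stop,
                 start_mode = start_mode, condition = condition,
                 sampling_fraction = sampling_fraction, seed = seed)

  for (attempt in seq_len(max_attempts)) {
    gen <- .bd_genealogy(lambda, mu, t_stop, n_stop, start_mode)
    ok <- switch(condition,
      none = TRUE,
      survival = gen$n_extant >= 1L,
      crown_both_survive = gen$both_survive)
    if (ok) {
      res <- .bd_reconstruct(gen, start_mode)
      res$attempts <- attempt
      res$config <- config
      class(res) <- "bd_sim"
      if (sampling_fraction < 1 && !res$degenerate)
        res <- subsample_tips(res, sampling_fraction)
      return(res)
    }
  }
  stop(sprintf(
    "rejection guard: condition '%s' not met within %d attempts (estimated acceptance probability < %.3g)",
    condition, max_attempts, 1 / max_attempts), call. = FALSE)
}

## One unconditioned realization. Returns the full genealogy: per lineage
## its parent (0 = no parent), birth/death times, and whether it is an
## extant leaf at the end. Splitting kills the parent lineage and creates
## two children, so every non-leaf lineage has exactly two children.
.bd_genealogy <- function(lambda, mu, t_stop, n_stop, start_mode) {
  n0 <- if (start_mode == "crown_pair") 2L else 1L
  cap <- 256L
  parent <- integer(cap); btime <- numeric(cap); dtime <- numeric(cap)
  is_leaf <- logical(cap); extant <- logical(cap)
  m <- n0
  parent[seq_len(n0)] <- 0L; btime[seq_len(n0)] <- 0; is_leaf[seq_len(n0)] <- TRUE
  alive <- seq_len(n0)
  total <- lambda + mu
  p_birth <- lambda / total
  tau <- 0
  repeat {
    k <- length(alive)
    if (k == 0L) break
    if (!is.null(n_stop) && k >= n_stop) break
    tau <- tau + stats::rexp(1L, total * k)
    if (!is.null(t_stop) && tau > t_stop) break
    pick <- sample.int(k, 1L)
    i <- alive[pick]
    dtime[i] <- tau
    if (stats::runif(1L) < p_birth) {
      if (m + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(btime) <- cap; length(dtime) <- cap
        length(is_leaf) <- cap; length(extant) <- cap
        is_leaf[is.na(is_leaf)] <- FALSE; extant[is.na(extant)] <- FALSE
      }
      kids <- m + 1:2
      parent[kids] <- i; btime[kids] <- tau; is_leaf[kids] <- TRUE
      is_leaf[i] <- FALSE
      m <- m + 2L
      alive <- c(alive[-pick], kids)
    } else {
      alive <- alive[-pick]
    }
  }
  t_end <- if (!is.null(t_stop)) t_stop else tau
  dtime[alive] <- t_end
  extant[alive] <- TRUE
  idx <- seq_len(m)
  ## does each basal lineage leave extant descendants?
  both <- if (start_mode == "crown_pair") {
    anc <- function(i) { while (parent[i] > 0L) i <- parent[i]; i }
    roots <- vapply(alive, anc, 0L)
    all(c(1L, 2L) %in% roots)
  } else NA
  list(parent = parent[idx], btime = btime[idx], dtime = dtime[idx],
       is_leaf = is_leaf[idx], extant = extant[idx], t_end = t_end,
       n_extant = length(alive), both_survive = both)
}

## Prune extinct lineages and build the reconstructed ultrametric phylo.
## Works bottom-up in reverse creation order (children always have larger
## indices than their parent). Each lineage is represented in the
## reconstructed tree by a tip (itself, if extant), by the node at which
## its two retained descendant lines diverged, or not at all.
.bd_reconstruct <- function(gen, start_mode) {
  m <- length(gen$parent)
  t_end <- gen$t_end
  lineages <- data.frame(parent = gen$parent, btime = gen$btime,
                         dtime = gen$dtime, extant = gen$extant)
  if (gen$n_extant < 2L) {
    return(list(tree = NULL, node_ages = numeric(0),
                n_extant = gen$n_extant, degenerate = TRUE,
                lineages = lineages, t_end = t_end,
                tip_lineage = integer(0)))
  }
  kids1 <- integer(m); kids2 <- integer(m)
  for (i in seq_len(m)) {
    p <- gen$parent[i]
    if (p > 0L) { if (kids1[p] == 0L) kids1[p] <- i else kids2[p] <- i }
  }
  rep_id <- integer(m)      # > 0 tip id, < 0 internal node id, 0 pruned
  rep_age <- numeric(m)
  n_tip <- 0L; n_int <- 0L
  tip_lineage <- integer(0)
  e_par <- integer(0); e_child <- integer(0); e_len <- numeric(0)
  int_age <- numeric(0)
  for (i in m:1) {
    if (gen$is_leaf[i]) {
      if (gen$extant[i]) {
        n_tip <- n_tip + 1L
        rep_id[i] <- n_tip
        tip_lineage[n_tip] <- i
      }
      next
    }
    c1 <- kids1[i]; c2 <- kids2[i]
    r1 <- rep_id[c1]; r2 <- rep_id[c2]
    if (r1 != 0L && r2 != 0L) {
      n_int <- n_int + 1L
      age <- t_end - gen$dtime[i]
      int_age[n_int] <- age
      e_par <- c(e_par, -n_int, -n_int)
      e_child <- c(e_child, r1, r2)
      e_len <- c(e_len, age - rep_age[c1], age - rep_age[c2])
      rep_id[i] <- -n_int
      rep_age[i] <- age
    } else if (r1 != 0L || r2 != 0L) {
      keep <- if (r1 != 0L) c1 else c2
      rep_id[i] <- rep_id[keep]
      rep_age[i] <- rep_age[keep]
    }
  }
  if (start_mode == "crown_pair") {
    r1 <- rep_id[1L]; r2 <- rep_id[2L]
    if (r1 != 0L && r2 != 0L) {
      n_int <- n_int + 1L
      int_age[n_int] <- t_end
      e_par <- c(e_par, -n_int, -n_int)
      e_child <- c(e_child, r1, r2)
      e_len <- c(e_len, t_end - rep_age[1L], t_end - rep_age[2L])
      root_rep <- -n_int
    } else {
      root_rep <- if (r1 != 0L) r1 else r2
    }
  } else {
    root_rep <- rep_id[1L]
  }
  if (root_rep > 0L)  # single surviving branch: not a 2-tip tree
    return(list(tree = NULL, node_ages = numeric(0),
                n_extant = gen$n_extant, degenerate = TRUE,
                lineages = lineages, t_end = t_end,
                tip_lineage = integer(0)))
  ## renumber: tips 1..n_tip; root first internal (ape convention n_tip+1)
  int_map <- integer(n_int)
  root_int <- -root_rep
  int_map[root_int] <- n_tip + 1L
  rest <- setdiff(seq_len(n_int), root_int)
  int_map[rest] <- n_tip + 1L + seq_along(rest)
  node_of <- function(x) {
    out <- integer(length(x))
    pos <- x > 0L
    out[pos] <- x[pos]
    out[!pos] <- int_map[-x[!pos]]
    out
  }
  edge <- cbind(node_of(e_par), node_of(e_child))
  storage.mode(edge) <- "integer"
  tree <- structure(
    list(edge = edge, edge.length = e_len, Nnode = n_int,
         tip.label = paste0("t", seq_len(n_tip))),
    class = c("chronogram", "phylo"))
  tree <- ape::reorder.phylo(tree, "cladewise")
  node_ages <- numeric(n_int)
  node_ages[int_map - n_tip] <- int_age
  names(node_ages) <- n_tip + seq_len(n_int)
  list(tree = tree, node_ages = node_ages, n_extant = gen$n_extant,
       degenerate = FALSE, lineages = lineages, t_end = t_end,
       tip_lineage = tip_lineage)
}

#' @export
print.bd_sim <- function(x, ...) {
  cat(sprintf(
    "birth-death simulation: lambda = %g, mu = %g, %s\n%d extant tip(s)%s; accepted after %d attempt(s)\n",
    x$config$lambda, x$config$mu,
    if (!is.null(x$config$t_stop)) sprintf("t_stop = %g Ma", x$config$t_stop)
    else sprintf("n_stop = %d", x$config$n_stop),
    x$n_extant, if (x$degenerate) " [degenerate: no 2-tip tree]" else "",
    x$attempts))
  invisible(x)
}

#' True divergence age of two simulated tips
#'
#' Looks up, in the recorded genealogy of a [simulate_bd()] result, the
#' event time at which the ancestral lines of two extant tips diverged,
#' and returns it as an age before present. This is read off the
#' simulation's event clock, independent of the branch lengths of the
#' reconstructed tree, so it can serve as an oracle for [crown_age()].
#'
#' @param sim a `"bd_sim"` object with a non-degenerate tree.
#' @param tip_a,tip_b tip labels of the reconstructed tree.
#' @return Age in Ma of the most recent common ancestor of the two tips.
#' @export
true_divergence_age <- function(sim, tip_a, tip_b) {
  stopifnot(inherits(sim, "bd_sim"))
  if (sim$degenerate) stop("degenerate simulation has no tree", call. = FALSE)
  labs <- sim$tree$tip.label
  ia <- match(tip_a, labs); ib <- match(tip_b, labs)
  if (anyNA(c(ia, ib))) stop("unknown tip label", call. = FALSE)
  par <- sim$lineages$parent
  path <- function(i) {
    p <- i
    while (i > 0L) { i <- par[i]; p <- c(p, i) }
    p
  }
  pa <- path(sim$tip_lineage[ia])
  pb <- path(sim$tip_lineage[ib])
  common <- intersect(pa, pb)
  mrca <- common[1L]  # paths are ordered tip -> root, first shared is deepest
  if (mrca == 0L) return(sim$t_end)  # crown node joining the two basal lineages
  sim$t_end - sim$lineages$dtime[mrca]
}

#' Randomly subsample the tips of a simulated chronogram
#'
#' Emulates incomplete taxon sampling: each extant tip is retained
#' independently with probability `rho`, and the tree is pruned to the
#' retained set (which can only keep or shallow the crown node, never
#' deepen it). If fewer than 2 tips survive the result is flagged
#' degenerate.
#'
#' @param sim a `"bd_sim"` object (or a `"phylo"` tree).
#' @param rho retention probability in `(0, 1]`.
#' @param seed optional integer seed.
#' @return Same type as the input; for a `"bd_sim"`, `node_ages` are
#'   recomputed from the pruned tree's (exact) branch lengths.
#' @export
subsample_tips <- function(sim, rho, seed = NULL) {
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tree <- if (inherits(sim, "bd_sim")) sim$tree else sim
  if (is.null(tree)) stop("degenerate simulation has no tree to subsample",
                          call. = FALSE)
  keep <- if (rho == 1) rep(TRUE, ape::Ntip(tree))
          else stats::runif(ape::Ntip(tree)) < rho
  if (!inherits(sim, "bd_sim")) {
    if (sum(keep) < 2L)
      stop("fewer than 2 tips retained at rho = ", rho, call. = FALSE)
    return(ape::keep.tip(tree, tree$tip.label[keep]))
  }
  out <- sim
  if (sum(keep) < 2L) {
    out$tree <- NULL
    out$node_ages <- numeric(0)
    out$n_extant <- sum(keep)
    out$degenerate <- TRUE
    out$tip_lineage <- sim$tip_lineage[keep]
    out$config$sampling_fraction <- rho
    return(out)
  }
  pruned <- ape::keep.tip(tree, tree$tip.label[keep])
  class(pruned) <- c("chronogram", "phylo")
  depths <- ape::node.depth.edgelength(pruned)
  crown <- max(depths[seq_len(ape::Ntip(pruned))])
  ages <- crown - depths[ape::Ntip(pruned) + seq_len(pruned$Nnode)]
  names(ages) <- ape::Ntip(pruned) + seq_len(pruned$Nnode)
  out$tree <- pruned
  out$node_ages <- ages
  out$n_extant <- ape::Ntip(pruned)
  out$tip_lineage <- sim$tip_lineage[match(pruned$tip.label, tree$tip.label)]
  out$config$sampling_fraction <- rho
  out
}

#' Monte-Carlo quantiles of crown clade size
#'
#' Simulates `reps` crown-conditioned birth-death clades at rates
#' reconstructed from `(r, epsilon)` via `lambda = r / (1 - epsilon)`,
#' `mu = epsilon * lambda`, and returns empirical quantiles of extant
#' clade size. This is the independent oracle against which the
#' closed-form [richness_interval()] bounds are validated; the heavy
#' event loop runs in compiled code, with all randomness drawn from R's
#' RNG so `seed` makes runs bit-identical.
#'
#' @inheritParams bd_aux
#' @param reps number of simulated clades (>= 100).
#' @param probs quantile probabilities, default `c(0.025, 0.975)`.
#' @param seed optional integer seed.
#' @param max_attempts per-clade rejection guard.
#' @return Named numeric vector of empirical quantiles (inverse-ECDF,
#'   integer-valued), with attributes `mean_size` and
#'   `acceptance_probability`.
#' @export
mc_clade_size_quantiles <- function(r, epsilon, t, reps = 1e5,
                                    probs = c(0.025, 0.975), seed = NULL,
                                    max_attempts = 1e6) {
  if (reps < 100) stop("reps must be >= 100", call. = FALSE)
  aux <- bd_aux(r, epsilon, t)  # validates r, epsilon, t
  lambda <- r / (1 - epsilon)
  mu <- epsilon * lambda
  if (!is.null(seed)) set.seed(seed)
  sizes <- bd_crown_sizes_cpp(as.integer(reps), lambda, mu, t,
                              as.double(max_attempts))
  q <- stats::quantile(sizes, probs = probs, type = 1, names = TRUE)
  attr(q, "mean_size") <- mean(sizes)
  attr(q, "acceptance_probability") <-
    2 * reps / attr(sizes, "attempts")
  attr(q, "theoretical_mean") <- 2 / (1 - aux$beta)
  q
}

#' Crown-conditioned clade sizes (raw draws)
#'
#' Lower-level access to the compiled simulator behind
#' [mc_clade_size_quantiles()]: returns the simulated clade sizes
#' themselves, for goodness-of-fit and coverage studies.
#'
#' @inheritParams mc_clade_size_quantiles
#' @return Integer vector of length `reps`.
#' @export
mc_clade_sizes <- function(r, epsilon, t, reps = 1e4, seed = NULL,
                           max_attempts = 1e6) {
  bd_aux(r, epsilon, t)
  lambda <- r / (1 - epsilon)
  mu <- epsilon * lambda
  if (!is.null(seed)) set.seed(seed)
  bd_crown_sizes_cpp(as.integer(reps), lambda, mu, t, as.double(max_attempts))
}
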