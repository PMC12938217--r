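#' The six-area cortical architecture graph
#'
#' Returns the between-area connection graph of the model: six areas (three
#' frontal/motor: M1, PM, PF; three parietal/somatosensory: S1, SA, PA) and
#' the twelve reciprocal projections implemented, each backed by documented
#' white-matter tracts. Edges are classified as `adjacent` (cortically
#' neighbouring areas), `jumping` (non-adjacent areas of the same system),
#' or `long` (long-distance links bridging the motor and somatosensory
#' systems).
#'
#' @return A list with `nodes` (character vector of 6 area names) and
#'   `edges` (a data.frame with columns `from`, `to`, `class`). Every edge
#'   is reciprocal; the pair ordering in the table is arbitrary.
#' @examples
#' g <- area_graph()
#' nrow(g$edges)           # 12
#' area_neighbors("PA")    # SA, S1, PM, PF
#' @export
area_graph <- function() {
  edges <- data.frame(
    from  = c("PF", "PM", "PF", "PA", "SA", "PA", "M1", "M1", "PM", "PM", "PA", "PA"),
    to    = c("PM", "M1", "M1", "SA", "S1", "S1", "S1", "SA", "S1", "SA", "PM", "PF"),
    class = c("adjacent", "adjacent", "jumping",
              "adjacent", "adjacent", "jumping",
              "adjacent", "long", "long", "long", "long", "long"),
    stringsAsFactors = FALSE
  )
  list(nodes = AREA_NAMES, edges = edges)
}

#' Neighbours of one area in the architecture graph
#'
#' @param area one of the six area names.
#' @return Character vector of areas reciprocally linked to `area`.
#' @export
area_neighbors <- function(area) {
  stopifnot(area %in% AREA_NAMES)
  e <- area_graph()$edges
  unique(c(e$to[e$from == area], e$from[e$to == area]))
}

#' Gaussian connection kernel over a square neighbourhood
#'
#' Link probability between two cells at grid offset (dr, dc) is
#' `min(1, p0 * exp(-d^2 / (2 sigma^2)))` with `d^2 = dr^2 + dc^2`, and 0
#' outside the n x n square centred on the topographically corresponding
#' cell.
#'
#' @param n odd square side length.
#' @param sigma Gaussian width in grid units.
#' @param p0 kernel peak.
#' @return data.frame with columns `dr`, `dc`, `p`.
#' @keywords internal
kernel_offsets <- function(n, sigma, p0) {
  h <- (n - 1L) %/% 2L
  off <- expand.grid(dr = -h:h, dc = -h:h)
  off$p <- pmin(1, p0 * exp(-(off$dr^2 + off$dc^2) / (2 * sigma^2)))
  off
}

local_row <- function(idx) (idx - 1L) %/% GRID_SIZE
local_col <- function(idx) (idx - 1L) %% GRID_SIZE

#' Sample one topographic projection between two 25 x 25 cell grids
#'
#' Draws the sparse, patchy, topographic links of a single projection.
#' `kind = "exc"` is a plastic excitatory-to-excitatory projection
#' (within- or between-area): each candidate (pre, post) pair within the
#' 19 x 19 neighbourhood square is linked independently with the
#' Gaussian-kernel probability, with weights uniform on
#' \[0, `w_init_max`\]. `kind = "inh"` is a local inhibitory-to-excitatory
#' projection: the same kernel sampling over the 5 x 5 neighbourhood, at
#' the fixed unlearned weight 1 -- together these surround projections
#' implement the local winner-take-all competition. `kind = "pair"` is
#' the deterministic column pairing that drives each inhibitory cell from
#' its own column's excitatory cell (weight `w_ei`). Grid borders are
#' clipped (no wraparound); topographic correspondence is the identity
#' map; self-synapses are excluded for within-area excitatory
#' projections.
#'
#' @param pre_area,post_area area names (equal for within-area projections).
#' @param kind `"exc"`, `"inh"`, or `"pair"`.
#' @param params a [model_params()] list.
#' @return data.frame with columns `pre`, `post` (1..625, local indices)
#'   and `w`. Uses the current RNG stream.
#' @export
sample_projection <- function(pre_area, post_area, kind = c("exc", "inh", "pair"),
                              params = model_params()) {
  kind <- match.arg(kind)
  stopifnot(pre_area %in% AREA_NAMES, post_area %in% AREA_NAMES)
  if (kind == "pair") {
    return(data.frame(pre = seq_len(CELLS_PER_AREA), post = seq_len(CELLS_PER_AREA),
                      w = params$w_ei))
  }
  n <- if (kind == "exc") params$n_exc_neighborhood else params$n_inh_neighborhood
  sigma <- if (kind == "exc") params$sigma_exc else params$sigma_inh
  p0 <- if (kind == "exc") params$p0_exc else params$p0_inh
  if (n > 2L * GRID_SIZE - 1L) stop("neighborhood larger than grid")
  off <- kernel_offsets(n, sigma, p0)
  n_off <- nrow(off)
  pre  <- rep(seq_len(CELLS_PER_AREA), times = n_off)
  dr   <- rep(off$dr, each = CELLS_PER_AREA)
  dc   <- rep(off$dc, each = CELLS_PER_AREA)
  p    <- rep(off$p,  each = CELLS_PER_AREA)
  r2 <- local_row(pre) + dr
  c2 <- local_col(pre) + dc
  ok <- r2 >= 0L & r2 < GRID_SIZE & c2 >= 0L & c2 < GRID_SIZE
  if (kind == "exc" && pre_area == post_area) ok <- ok & !(dr == 0L & dc == 0L)
  pre <- pre[ok]; r2 <- r2[ok]; c2 <- c2[ok]; p <- p[ok]
  hit <- runif(length(pre)) < p
  pre <- pre[hit]; r2 <- r2[hit]; c2 <- c2[hit]
  w <- if (kind == "exc") runif(length(pre), 0, params$w_init_max)
       else rep(1, length(pre))   # inhibitory weights are fixed and never learned
  data.frame(pre = pre,
             post = r2 * GRID_SIZE + c2 + 1L,
             w = w)
}

area_index <- function(area) match(area, AREA_NAMES)

#' Which area a global excitatory cell index belongs to
#' @param idx global cell index in 1..3750.
#' @return Integer area index in 1..6 (order M1, PM, PF, S1, SA, PA).
#' @export
area_of <- function(idx) (as.integer(idx) - 1L) %/% CELLS_PER_AREA + 1L

#' Initialize a network: architecture, connectivity, and zeroed cell states
#'
#' Instantiates all within-area recurrent excitatory projections, all
#' between-area projections of the architecture graph (both directions of
#' every edge), the local excitatory-to-inhibitory projections, and the
#' fixed column-wise inhibitory pairing; all membrane potentials, outputs,
#' rate estimates and global-inhibition accumulators start at zero. The
#' construction is fully reproducible from `seed` (sub-stream
#' `"connectivity"` of the master seed).
#'
#' The returned network has reference semantics (an environment): phase
#' runners advance its state in place. Use [net_copy()] for an independent
#' deep copy (e.g. the Phase II "twins").
#'
#' @param params a [model_params()] list.
#' @param seed integer master seed.
#' @return An environment of class `"canet_network"` holding parameters,
#'   the sparse synapse set, and all cell-state vectors.
#' @examples
#' \donttest{
#' net <- init_network(model_params(), seed = 1)
#' summary(net$conn$ee$w)
#' }
#' @export
init_network <- function(params = model_params(), seed = 1L) {
  validate_params(params)
  set.seed(derive_seed(seed, "connectivity"))
  g <- area_graph()

  pre_l <- list(); post_l <- list(); w_l <- list(); between_l <- list()
  # within-area recurrent projections, fixed area order
  for (a in AREA_NAMES) {
    s <- sample_projection(a, a, "exc", params)
    o <- (area_index(a) - 1L) * CELLS_PER_AREA
    pre_l[[length(pre_l) + 1L]] <- s$pre + o
    post_l[[length(post_l) + 1L]] <- s$post + o
    w_l[[length(w_l) + 1L]] <- s$w
    between_l[[length(between_l) + 1L]] <- rep(FALSE, nrow(s))
  }
  # between-area projections, both directions of each documented edge
  for (k in seq_len(nrow(g$edges))) {
    for (dir in 1:2) {
      a <- if (dir == 1) g$edges$from[k] else g$edges$to[k]
      b <- if (dir == 1) g$edges$to[k] else g$edges$from[k]
      s <- sample_projection(a, b, "exc", params)
      pre_l[[length(pre_l) + 1L]] <- s$pre + (area_index(a) - 1L) * CELLS_PER_AREA
      post_l[[length(post_l) + 1L]] <- s$post + (area_index(b) - 1L) * CELLS_PER_AREA
      w_l[[length(w_l) + 1L]] <- s$w
      between_l[[length(between_l) + 1L]] <- rep(TRUE, nrow(s))
    }
  }
  pre <- unlist(pre_l); post <- unlist(post_l)
  w <- unlist(w_l); between <- unlist(between_l)
  ord <- order(pre, post)
  pre <- pre[ord]; post <- post[ord]; w <- w[ord]; between <- between[ord]
  if (anyDuplicated(paste(pre, post))) {
    # cannot happen by construction (one draw per candidate pair) but the
    # synapse-set invariant is cheap to enforce
    stop("duplicate (pre, post) synapse generated")
  }
  row_ptr <- c(0L, cumsum(tabulate(pre, nbins = N_EXC)))
  csc_order <- order(post, pre)
  csc_pre <- pre[csc_order]
  col_ptr <- c(0L, cumsum(tabulate(post, nbins = N_EXC)))

  # local inhibitory surround: inhibitory cells project onto the
  # excitatory cells of their 5 x 5 neighbourhood at fixed weight 1
  ie_pre_l <- list(); ie_post_l <- list(); ie_w_l <- list()
  for (a in AREA_NAMES) {
    s <- sample_projection(a, a, "inh", params)
    o <- (area_index(a) - 1L) * CELLS_PER_AREA
    ie_pre_l[[length(ie_pre_l) + 1L]] <- s$pre + o
    ie_post_l[[length(ie_post_l) + 1L]] <- s$post + o
    ie_w_l[[length(ie_w_l) + 1L]] <- s$w
  }
  ie_pre <- unlist(ie_pre_l); ie_post <- unlist(ie_post_l); ie_w <- unlist(ie_w_l)
  ord <- order(ie_pre, ie_post)
  ie_pre <- ie_pre[ord]; ie_post <- ie_post[ord]; ie_w <- ie_w[ord]
  ie_row_ptr <- c(0L, cumsum(tabulate(ie_pre, nbins = N_EXC)))

  net <- new.env(parent = emptyenv())
  net$par <- params
  net$seed <- as.integer(seed)
  net$conn <- list(
    ee = list(pre = as.integer(pre), post = as.integer(post), w = as.numeric(w),
              between = as.logical(between), row_ptr = as.integer(row_ptr),
              csc_order = as.integer(csc_order), csc_pre = as.integer(csc_pre),
              col_ptr = as.integer(col_ptr)),
    # ie: inhibitory -> excitatory surround links; the excitatory -> inhibitory
    # drive is the implicit column pairing at weight w_ei
    ie = list(pre = as.integer(ie_pre), post = as.integer(ie_post),
              w = as.numeric(ie_w), row_ptr = as.integer(ie_row_ptr))
  )
  net$V_e <- numeric(N_EXC)
  net$V_i <- numeric(N_EXC)
  net$phi_e <- integer(N_EXC)
  net$phi_i <- numeric(N_EXC)
  net$omega <- numeric(N_EXC)
  net$omega_E <- numeric(N_EXC)
  net$omega_G <- numeric(6L)
  net$R_signal <- 0
  net$t <- 0L
  class(net) <- "canet_network"
  net
}

#' Deep copy of a network
#'
#' Networks have reference semantics; this returns an independent copy
#' (identical weights and cell states, separate storage), as used to create
#' the Phase II twin networks.
#'
#' @param net a `"canet_network"`.
#' @return A new `"canet_network"` environment.
#' @export
net_copy <- function(net) {
  stopifnot(inherits(net, "canet_network"))
  snap <- mget(ls(net, all.names = TRUE), envir = net)
  # serialize round-trip guarantees fresh storage: the C++ engine mutates
  # vectors in place, so twins must not share any SEXP with the original
  snap <- unserialize(serialize(snap, NULL))
  out <- list2env(snap, parent = emptyenv())
  class(out) <- "canet_network"
  out
}

#' @export
print.canet_network <- function(x, ...) {
  cat("<canet_network> 6 areas x", CELLS_PER_AREA, "columns;",
      length(x$conn$ee$w), "plastic synapses; t =", x$t, "\n")
  invisible(x)
}

#' Save / load a full network snapshot
#'
#' Serializes the complete network (weights, all cell states, step counter,
#' and the current .Random.seed if present) so a run can be replayed
#' exactly. Round-trips are bit-exact.
#'
#' @param net a `"canet_network"`.
#' @param path file path for the snapshot.
#' @return `save_network` returns `path` invisibly; `load_network` returns
#'   the restored network.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "canet_network"))
  snap <- mget(ls(net, all.names = TRUE), envir = net)
  snap$.rng <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  saveRDS(snap, path)
  invisible(path)
}

#' @rdname save_network
#' @param restore_rng if `TRUE`, also restores the saved RNG state.
#' @export
load_network <- function(path, restore_rng = FALSE) {
  snap <- readRDS(path)
  rng <- snap$.rng
  snap$.rng <- NULL
  net <- list2env(snap, parent = emptyenv())
  class(net) <- "canet_network"
  if (restore_rng && !is.null(rng)) assign(".Random.seed", rng, envir = globalenv())
  net
}
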