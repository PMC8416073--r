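#' Affinity model on an integer shape space
#'
#' B-cell receptor genotypes live on a low-dimensional integer lattice; the
#' affinity of a receptor for the antigen is a Gaussian function of its
#' Euclidean distance d to the optimal genotype, a = exp(-d^2 / gamma^2),
#' so a is 1 at the optimum and strictly decreasing in d. Somatic
#' hypermutation moves the genotype by one unit step in a random coordinate.
#'
#' @param dimension Number of shape-space coordinates (default 4).
#' @param gamma Width of the Gaussian affinity kernel (default 2.8).
#' @param optimum Integer coordinates of the optimal genotype (default the
#'   origin).
#' @return An object of class \code{affinity_model}.
#' @export
affinity_model <- function(dimension = 4, gamma = 5, optimum = NULL) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (is.null(optimum)) optimum <- rep(0L, dimension)
  if (length(optimum) != dimension)
    stop("optimum must have length `dimension`")
  structure(list(dimension = as.integer(dimension), gamma = gamma,
                 optimum = as.numeric(optimum)),
            class = "affinity_model")
}

#' Affinity of a receptor genotype
#'
#' @param position Integer coordinate vector (one genotype) or a matrix with
#'   one genotype per row.
#' @param model An \code{\link{affinity_model}}.
#' @return Affinity in \code{(0, 1]} (vectorized over rows).
#' @export
#' @examples
#' m <- affinity_model()
#' affinity(c(0, 0, 0, 0), m)  # 1 at the optimum
affinity <- function(position, model = affinity_model()) {
  if (is.matrix(position)) {
    if (ncol(position) != model$dimension)
      stop("genotype dimension (", ncol(position),
           ") does not match the model (", model$dimension, ")")
    d2 <- rowSums(sweep(position, 2, model$optimum)^2)
  } else {
    if (length(position) != model$dimension)
      stop("genotype dimension (", length(position),
           ") does not match the model (", model$dimension, ")")
    d2 <- sum((position - model$optimum)^2)
  }
  exp(-d2 / model$gamma^2)
}

#' Apply one round of somatic hypermutation
#'
#' With probability \code{p_mut} the genotype takes a unit step: one
#' coordinate chosen uniformly moves by +1 or -1 with equal probability.
#' Uses R's global RNG stream.
#'
#' @param position Integer coordinate vector.
#' @param p_mut Mutation probability per division, in \code{[0, 1]}.
#' @return List with the (possibly) new \code{position} and logical
#'   \code{mutated}.
#' @export
mutate_bcr <- function(position, p_mut = 0.5) {
  if (p_mut < 0 || p_mut > 1) stop("p_mut must lie in [0, 1]")
  if (stats::runif(1) >= p_mut)
    return(list(position = position, mutated = FALSE))
  k <- sample.int(length(position), 1L)
  position[k] <- position[k] + if (stats::runif(1) < 0.5) 1L else -1L
  list(position = position, mutated = TRUE)
}

# Vectorized hypermutation over the rows of a genotype matrix; used by the
# engine at division time. Draw order: one uniform per cell (mutate or not),
# then one coordinate index and one sign per mutating cell.
mutate_bcr_rows <- function(pos, p_mut) {
  n <- nrow(pos)
  if (n == 0L) return(list(position = pos, mutated = logical(0)))
  hit <- stats::runif(n) < p_mut
  m <- sum(hit)
  if (m > 0L) {
    k <- sample.int(ncol(pos), m, replace = TRUE)
    s <- ifelse(stats::runif(m) < 0.5, 1, -1)
    idx <- cbind(which(hit), k)
    pos[idx] <- pos[idx] + s
  }
  list(position = pos, mutated = hit)
}

#' Sample a founder receptor genotype
#'
#' Draws a random direction, scales it to a target distance sampled uniformly
#' from \code{dist_range}, and rounds to the lattice, retrying until the
#' realized Euclidean distance falls inside the range. Founder cells start
#' well away from the optimum so that affinity maturation has room to act.
#'
#' @param model An \code{\link{affinity_model}}.
#' @param dist_range Length-2 numeric, inclusive distance bounds
#'   (default \code{c(5, 10)}).
#' @return Integer coordinate vector.
#' @export
founder_gene <- function(model = affinity_model(), dist_range = c(5, 10)) {
  stopifnot(length(dist_range) == 2L, dist_range[1] > 0,
            dist_range[2] >= dist_range[1])
  for (i in 1:1000) {
    target <- stats::runif(1, dist_range[1], dist_range[2])
    v <- stats::rnorm(model$dimension)
    x <- round(v * target / sqrt(sum(v^2)))
    d <- sqrt(sum((x - model$optimum)^2))
    if (d >= dist_range[1] && d <= dist_range[2]) return(as.integer(x))
  }
  stop("could not sample a founder genotype in the requested distance range")
}
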