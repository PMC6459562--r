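#' Degree profile of an edge-typed regular graph
#'
#' Every node of the graphs considered here has total degree `k`, split into
#' `g[i]` neighbours reached along edges of type `i` (so `sum(g) == k`). The
#' pair `(k; g1, ..., gn)` is all the local structure the analytic theory
#' needs, and is shared by every node of the graph.
#'
#' @param k Total degree, a single integer `>= 3`. The closed-form structure
#'   coefficients contain a `(k - 2)` factor and are only defined for
#'   `k >= 3`.
#' @param g Integer vector of per-type degrees, one entry per edge type, all
#'   positive, summing to `k`. Length `n` must satisfy `1 <= n <= k`.
#' @return An object of class `"degree_profile"`: a list with elements `k`,
#'   `g` and `n = length(g)`.
#' @examples
#' degree_profile(6, c(3, 3))
#' degree_profile(4, c(3, 1))
#' @export
degree_profile <- function(k, g) {
  k <- as.integer(k)
  g <- as.integer(g)
  if (length(k) != 1L || is.na(k) || k < 3L)
    stop("'k' must be a single integer >= 3", call. = FALSE)
  if (length(g) < 1L || length(g) > k)
    stop("number of edge types must be between 1 and k", call. = FALSE)
  if (anyNA(g) || any(g < 1L))
    stop("all per-type degrees 'g' must be positive integers", call. = FALSE)
  if (sum(g) != k)
    stop("per-type degrees must sum to k (got sum(g) = ", sum(g),
         ", k = ", k, ")", call. = FALSE)
  structure(list(k = k, g = g, n = length(g)), class = "degree_profile")
}

#' @export
print.degree_profile <- function(x, ...) {
  cat("Degree profile: k =", x$k, " g = (", paste(x$g, collapse = ", "),
      ") with", x$n, if (x$n == 1L) "edge type\n" else "edge types\n")
  invisible(x)
}

as_profile <- function(profile) {
  if (inherits(profile, "degree_profile")) return(profile)
  stop("expected a 'degree_profile' object", call. = FALSE)
}

#' Enumerate all neighbourhood configurations of a profile
#'
#' A configuration `(s1, ..., sn)` counts, for each edge type `i`, how many of
#' the `g[i]` type-`i` neighbours of a focal node play strategy A. The full
#' lattice has `prod(g + 1)` configurations.
#'
#' @param profile A [degree_profile()].
#' @return An integer matrix with one row per configuration and `n` columns,
#'   in lexicographic order of `(s1, ..., sn)` (the first coordinate varies
#'   slowest).
#' @examples
#' config_grid(degree_profile(4, c(3, 1)))
#' @export
config_grid <- function(profile) {
  profile <- as_profile(profile)
  n <- profile$n
  cols <- rev(expand.grid(rev(lapply(profile$g, function(gi) 0:gi)),
                          KEEP.OUT.ATTRS = FALSE))
  m <- as.matrix(cols)
  dimnames(m) <- list(NULL, paste0("s", seq_len(n)))
  storage.mode(m) <- "integer"
  m
}

#' Row index of a configuration within [config_grid()]
#'
#' @param profile A [degree_profile()].
#' @param s Integer vector, one configuration, `0 <= s[i] <= g[i]`.
#' @return A single integer index into the rows of `config_grid(profile)`.
#' @keywords internal
config_index <- function(profile, s) {
  profile <- as_profile(profile)
  s <- as.integer(s)
  if (length(s) != profile$n || anyNA(s) || any(s < 0L) || any(s > profile$g))
    stop("invalid configuration for this profile", call. = FALSE)
  idx <- 0L
  for (j in seq_len(profile$n)) idx <- idx * (profile$g[j] + 1L) + s[j]
  idx + 1L
}

validate_config <- function(profile, s) {
  s <- as.integer(s)
  if (length(s) != profile$n || anyNA(s) || any(s < 0L) || any(s > profile$g))
    stop("invalid configuration: need 0 <= s_i <= g_i for each type",
         call. = FALSE)
  s
}
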