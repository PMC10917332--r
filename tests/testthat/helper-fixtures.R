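# Small shared fixtures built in code.

# A minimal valid specimen table.
toy_dataset <- function(n1 = 6, n2 = 6, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    taxon_id = sprintf("t%02d", seq_len(n1 + n2)),
    md_mm = exp(rnorm(n1 + n2, log(20), 0.5)),
    cg = c(runif(n1, 0.3, 0.6), runif(n2, 0.7, 0.99)),
    fly_code = "0",
    dive_code = rep(c("0", "2"), c(n1, n2)),
    status = "unknown",
    role = "train"
  )
}

# Balanced labeled Gaussian clouds as a plain points data frame.
toy_points <- function(n = 30, sigma = 0.5, d = 1.7, seed = 1) {
  sim_two_class(n, sigma = sigma, d = d, seed = seed)
}

# A star tree with unit branch lengths over the given tip labels.
star_tree <- function(tips) {
  tr <- ape::stree(length(tips), type = "star")
  tr$tip.label <- tips
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# A reproducible pure-birth tree over the given tip labels.
toy_tree <- function(tips, seed = 1) {
  set.seed(seed)
  tr <- ape::rphylo(length(tips), birth = 1, death = 0)
  tr$tip.label <- tips
  tr
}

# Brute-force minimum-Mahalanobis classifier used as an independent oracle.
mahalanobis_oracle <- function(fit, X) {
  d1 <- stats::mahalanobis(X, fit$centroids[1, ], fit$pooled_cov)
  d2 <- stats::mahalanobis(X, fit$centroids[2, ], fit$pooled_cov)
  ifelse(d2 < d1, 2L, 1L)
}
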