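# Independent oracles used to cross-check the package implementations.
# These are deliberately written as plain loops from first principles and
# never call the code paths they verify.

# Conditional two-sided exact p by direct enumeration: the sum of n iid
# NB(mu, phi) counts is NB with size n/phi; given the total, weight each
# split by the product of the two group-sum pmfs at the null mean and sum
# the weights of all splits no more probable than the observed one.
oracle_nb_split_p <- function(sa, sb, na, nb, phi) {
  total <- sa + sb
  if (total == 0) return(1)
  mu0 <- total / (na + nb)
  w <- numeric(total + 1)
  for (a in 0:total) {
    w[a + 1] <- if (phi == 0) {
      dpois(a, na * mu0) * dpois(total - a, nb * mu0)
    } else {
      dnbinom(a, size = na / phi, mu = na * mu0) *
        dnbinom(total - a, size = nb / phi, mu = nb * mu0)
    }
  }
  sum(w[w <= w[sa + 1]]) / sum(w)
}

# Closed-form binomial exact test (the phi -> 0 limit): conditional on
# the total, the group-A sum is Binomial(T, na / (na + nb)).
oracle_binom_p <- function(sa, total, prob) {
  w <- dbinom(0:total, total, prob)
  sum(w[w <= w[sa + 1] * (1 + 1e-12)]) / sum(w)
}

# Topological overlap by triple loop over the definition.
oracle_tom <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  tom
}

# All-pairs >=1 bp interval overlap count (members of a overlapping any
# member of b).
oracle_overlap_n <- function(a, b) {
  n <- 0
  for (i in seq_len(nrow(a))) {
    hit <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$start[i] < b$end[j] &&
          a$end[i] > b$start[j]) {
        hit <- TRUE
        break
      }
    }
    if (hit) n <- n + 1
  }
  n
}

# Random disjoint interval set on a toy genome (0-based half-open).
random_dmr_set <- function(n, chroms = c("chr1", "chr2"), max_bp = 1e5) {
  starts <- sort(sample.int(max_bp %/% 1000 - 2, n)) * 1000
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = starts,
    end = starts + sample(1:3, n, replace = TRUE) * 1000
  )
}

# Small default study used across pipeline tests.
tiny_config <- function(...) {
  defaults <- list(
    n_pairs_per_sex = 6, n_chromosomes = 2, chrom_length_bp = 2e5,
    n_planted_dmrs = 4, n_latent_modules = 1, module_size_windows = 20,
    fraction_discordant = c(pa = 1, walkability = 0.5, bmi = 0.5))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
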