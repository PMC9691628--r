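# Correlation-network stage: adjacency, TOM, module detection,
# eigengenes, merging, module-trait statistics.

test_that("unsigned adjacency is |cor|^power with unit diagonal", {
  x <- cbind(a = 1:10, b = 10:1, c = (1:10) * 2)
  a <- wcna_adjacency(x, power = 6)
  expect_equal(unname(diag(a)), rep(1, 3))
  expect_equal(a["a", "b"], 1)   # perfect anti-correlation, unsigned
  expect_equal(a["a", "c"], 1)
  # r = -0.5 at beta = 6 -> 0.5^6
  # construct exact r = -0.5 via residual orthogonalisation
  set.seed(51)
  z1 <- rnorm(200)
  e <- residuals(lm(rnorm(200) ~ z1))
  y <- -0.5 * scale(z1)[, 1] + sqrt(0.75) * scale(e)[, 1]
  a2 <- wcna_adjacency(cbind(z1, y), power = 6)
  expect_equal(a2[1, 2], 0.5^6, tolerance = 1e-10)
  expect_warning(wcna_adjacency(cbind(z1, rep(1, 200)), power = 6),
                 "zero-variance")
})

test_that("TOM matches its defining formula and the brute-force oracle", {
  # 2-node network with a = 0.5: TOM = 0.5 / (0.5 + 1 - 0.5) = 0.5
  a <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(tom_similarity(a)[1, 2], 0.5)
  # complete graph with all a = 1 -> all TOM = 1
  ones <- matrix(1, 5, 5)
  expect_true(all(tom_similarity(ones) == 1))
  # random 6-10 node matrices against the triple loop, to 1e-12
  set.seed(61)
  for (i in 1:12) {
    n <- sample(6:10, 1)
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- tom_similarity(a)
    expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_true(isSymmetric(tom))
    expect_equal(unname(diag(tom)), rep(1, n))
  }
  expect_error(tom_similarity(matrix(runif(9), 3)), "symmetric")
})

test_that("module detection recovers planted correlation blocks", {
  set.seed(71)
  n <- 40
  f1 <- rnorm(n); f2 <- rnorm(n)
  block <- function(f, k) sapply(1:k, function(i) 2 * f + 0.9 * rnorm(n))
  x <- cbind(block(f1, 50), block(f2, 50), matrix(rnorm(n * 60), n))
  colnames(x) <- paste0("w", seq_len(ncol(x)))
  a <- wcna_adjacency(x, power = 6)
  mods <- detect_modules(1 - tom_similarity(a), min_module_size = 30)
  # raw dendrogram cut: each planted block lands entirely in one module
  # (with possibly a few weakly-correlated stragglers attached), the two
  # blocks stay apart, and noise is predominantly grey
  m1 <- mods$module[1:50]; m2 <- mods$module[51:100]
  expect_equal(length(unique(m1)), 1L)
  expect_equal(length(unique(m2)), 1L)
  expect_false(unique(m1) == unique(m2))
  expect_gte(mean(mods$module[101:160] == "grey"), 0.75)
  # full driver adds the kME membership cleanup: recovery is then sharp
  fit <- wcna_modules(x, network_config(power = 6), seed = 1)
  truth <- rep(c("m1", "m2", "noise"), c(50, 50, 60))
  expect_gte(mclust::adjustedRandIndex(fit$assignment$module, truth), 0.9)
  expect_true(all(fit$assignment$module[101:160] == "grey"))
})

test_that("independent noise yields no modules at all", {
  set.seed(72)
  x <- matrix(rnorm(30 * 200), nrow = 30)
  colnames(x) <- paste0("w", 1:200)
  a <- wcna_adjacency(x, power = 6)
  mods <- detect_modules(1 - tom_similarity(a), min_module_size = 30)
  expect_true(all(mods$module == "grey"))
})

test_that("duplicate-profile windows always land in the same module", {
  set.seed(73)
  n <- 20
  f <- rnorm(n)
  x <- cbind(sapply(1:40, function(i) f + 0.3 * rnorm(n)))
  x <- cbind(x, x[, 1], x[, 1])  # exact duplicates of window 1
  colnames(x) <- paste0("w", seq_len(ncol(x)))
  a <- wcna_adjacency(x, power = 6)
  mods <- detect_modules(1 - tom_similarity(a), min_module_size = 10)
  expect_equal(mods$module[41], mods$module[1])
  expect_equal(mods$module[42], mods$module[1])
})

test_that("eigengene is the top left singular vector with fixed sign", {
  set.seed(81)
  x <- matrix(rnorm(15 * 8), nrow = 15,
              dimnames = list(NULL, paste0("w", 1:8)))
  e <- module_eigengene(x, paste0("w", 1:8))
  # explicit SVD oracle on the z-scored matrix
  z <- scale(x)
  sv <- svd(z)
  oracle <- sv$u[, 1]
  if (mean(cor(oracle, z)) < 0) oracle <- -oracle
  expect_equal(e, oracle, tolerance = 1e-10)
  expect_equal(sum(e^2), 1)
  # optimality: explains at least as much variance as any member profile
  proj_var <- function(d) sum((t(z) %*% d)^2)
  expect_true(all(vapply(1:8, function(j) {
    proj_var(e) >= proj_var(z[, j] / sqrt(sum(z[, j]^2)))
  }, logical(1))))
  # invariant (up to sign) to member order and affine member rescaling
  e2 <- module_eigengene(x[, sample(8)], paste0("w", 1:8))
  expect_equal(abs(cor(e, e2)), 1, tolerance = 1e-10)
  x2 <- x; x2[, 3] <- 5 * x2[, 3] - 7
  e3 <- module_eigengene(x2, paste0("w", 1:8))
  expect_equal(abs(cor(e, e3)), 1, tolerance = 1e-10)
  # identical profiles: eigengene proportional to the shared profile
  xx <- matrix(rep(rnorm(10), 4), ncol = 4,
               dimnames = list(NULL, paste0("d", 1:4)))
  ed <- module_eigengene(xx, paste0("d", 1:4))
  expect_equal(abs(cor(ed, xx[, 1])), 1, tolerance = 1e-10)
  # single-member module: the z-scored profile itself (unit norm)
  e1 <- module_eigengene(x, "w1")
  expect_equal(abs(cor(e1, x[, 1])), 1, tolerance = 1e-12)
})

test_that("module merging iterates to a fixed point through chains", {
  set.seed(91)
  n <- 30
  f <- rnorm(n)
  # three modules with eigengene correlations approx A~B 0.8, B~C 0.8,
  # A~C lower: the chain must collapse into one module
  fa <- f + 0.45 * rnorm(n)
  fb <- f
  fc <- f + 0.45 * rnorm(n)
  mk <- function(g, tag) {
    m <- sapply(1:10, function(i) g + 0.05 * rnorm(n))
    colnames(m) <- paste0(tag, 1:10)
    m
  }
  x <- cbind(mk(fa, "a"), mk(fb, "b"), mk(fc, "c"))
  assignment <- tibble::tibble(window = colnames(x),
                               module = rep(c("A", "B", "C"), each = 10))
  merged <- merge_modules(x, assignment, merge_cut_height = 0.25)
  expect_equal(length(unique(merged$module)), 1L)
  # far-apart modules stay separate
  y <- cbind(mk(rnorm(n), "a"), mk(rnorm(n), "b"))
  asg2 <- tibble::tibble(window = colnames(y),
                         module = rep(c("A", "B"), each = 10))
  expect_equal(merge_modules(y, asg2, 0.25)$module, asg2$module)
})

test_that("module-trait correlation uses the Student-t closed form", {
  set.seed(101)
  n <- 20
  me <- matrix(rnorm(n * 2), ncol = 2, dimnames = list(NULL, c("blue", "red")))
  traits <- data.frame(t1 = rnorm(n), t2 = me[, 1] + 0.2 * rnorm(n))
  mt <- module_trait_cor(me, traits)
  r <- cor(me[, "blue"], traits$t2)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(mt$p["blue", "t2"], 2 * pt(abs(tstat), n - 2, lower.tail = FALSE))
  # trait equal to an eigengene -> r = 1, p ~ 0
  mt2 <- module_trait_cor(me, data.frame(self = me[, "red"]))
  expect_equal(mt2$r["red", "self"], 1)
  expect_lt(mt2$p["red", "self"], 1e-12)
  # r = 0 -> p = 1 (t = 0)
  expect_equal(cor_pvalue_student(0, 10), 1)
  # constant trait -> NA with warning
  expect_warning(mt3 <- module_trait_cor(me, data.frame(k = rep(1, n))),
                 "constant")
  expect_true(all(is.na(mt3$r[, "k"])))
})

test_that("module-trait p agrees with a label-permutation null", {
  # small permutation check here; the 100k-permutation grid runs in the
  # acceptance suite
  set.seed(111)
  n <- 20
  x <- rnorm(n)
  y <- 0.55 * scale(x)[, 1] + sqrt(1 - 0.55^2) * rnorm(n)
  r_obs <- cor(x, y)
  p_closed <- cor_pvalue_student(r_obs, n)
  B <- 20000
  perm <- replicate(B, abs(cor(x, sample(y))))
  p_perm <- (sum(perm >= abs(r_obs)) + 1) / (B + 1)
  se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(p_closed - p_perm), 3 * se + 1e-4)
})

test_that("blockwise driver matches single-block detection and reunites splits", {
  set.seed(121)
  n <- 30
  f1 <- rnorm(n); f2 <- rnorm(n)
  mk <- function(f, k, tag) {
    m <- sapply(1:k, function(i) 2 * f + 0.7 * rnorm(n))
    colnames(m) <- paste0(tag, 1:k)
    m
  }
  x <- cbind(mk(f1, 40, "p"), mk(f2, 40, "q"), matrix(rnorm(n * 40), n))
  colnames(x)[81:120] <- paste0("n", 1:40)
  cfg_small <- network_config(power = 6, min_module_size = 15)
  single <- wcna_modules(x, cfg_small, seed = 3)
  # windows below max_block_size: single block
  expect_equal(single$n_blocks, 1L)
  # force tiny blocks: planted modules must survive re-merging
  cfg_blocked <- network_config(power = 6, min_module_size = 15,
                                max_block_size = 45)
  blocked <- suppressWarnings(wcna_modules(x, cfg_blocked, seed = 3))
  expect_gt(blocked$n_blocks, 1L)
  truth <- rep(c("p", "q", "noise"), each = 40)
  expect_gte(mclust::adjustedRandIndex(blocked$assignment$module, truth), 0.8)
  # block partition is seed-deterministic
  again <- suppressWarnings(wcna_modules(x, cfg_blocked, seed = 3))
  expect_identical(blocked$assignment, again$assignment)
})
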