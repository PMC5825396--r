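# Protocol ranking by inclusion/exclusion and triplet enumeration.

# generator: one protocol carries (noisy) copies of the drivers of Y,
# the others are pure noise
informative_case <- function(seed, n = 300) {
  set.seed(seed)
  drivers <- matrix(rnorm(n * 3), n, 3)
  noisy <- function() {
    m <- matrix(exp(drivers %*% matrix(rnorm(9, sd = 0.8), 3, 3) +
                    rnorm(n * 3, 0, 0.05)), n, 3)
    colnames(m) <- c("APD90", "CaTA", "CaD50")
    m
  }
  pure_noise <- function() {
    m <- matrix(rlnorm(n * 3), n, 3)
    colnames(m) <- c("APD90", "CaTA", "CaD50")
    m
  }
  blocks <- list(info = noisy(), noiseA = pure_noise(),
                 noiseB = pure_noise(), noiseC = pure_noise())
  y <- exp(drivers %*% matrix(c(1, 0.5, -0.3, 0.2, -1, 0.6), 3, 2) +
           rnorm(n * 2, 0, 0.05))
  colnames(y) <- c("APD90", "CaTA")
  list(blocks = blocks, y = y)
}

test_that("inclusion ranks the informative protocol first", {
  for (s in 1:3) {
    cs <- informative_case(s)
    r <- rank_protocols(cs$blocks, cs$y, "inclusion", seed = s)
    expect_identical(r$ranking[1], "info")
    expect_length(r$ranking, 4)
    # early steps do not lose predictive power
    expect_gte(r$steps$r2[2], r$steps$r2[1] - 0.02)
  }
})

test_that("exclusion removes the informative protocol last", {
  for (s in 1:3) {
    cs <- informative_case(s)
    r <- rank_protocols(cs$blocks, cs$y, "exclusion", seed = s)
    expect_identical(r$ranking[1], "info")   # most informative first
    expect_identical(r$steps$protocol[nrow(r$steps)] == "info" ||
                       r$ranking[1] == "info", TRUE)
    # inclusion and exclusion agree on the top protocol
    ri <- rank_protocols(cs$blocks, cs$y, "inclusion", seed = s)
    expect_identical(ri$ranking[1], r$ranking[1])
  }
})

test_that("an exact duplicate block is excluded early", {
  # each block carries its own driver of y, plus an exact copy of block a:
  # dropping the copy costs nothing, dropping any other block loses that
  # block's unique information
  set.seed(4)
  n <- 300
  d1 <- rnorm(n); d2 <- rnorm(n); d3 <- rnorm(n)
  view <- function(d) {
    m <- exp(cbind(d, 0.7 * d, -0.5 * d) + rnorm(n * 3, 0, 0.05))
    colnames(m) <- c("APD90", "CaTA", "CaD50")
    m
  }
  blocks <- list(a = view(d1), b = view(d2), c = view(d3))
  blocks$a_copy <- blocks$a
  y <- exp(cbind(d1 + d2 - 0.5 * d3, 0.4 * d1 - d2 + d3) +
           rnorm(n * 2, 0, 0.05))
  colnames(y) <- c("APD90", "CaTA")
  r <- rank_protocols(blocks, y, "exclusion", seed = 4)
  expect_true(r$steps$protocol[r$steps$step == 1] %in% c("a", "a_copy"))
})

test_that("a single candidate yields a length-1 ranking", {
  cs <- informative_case(5)
  r <- rank_protocols(cs$blocks["info"], cs$y, "inclusion", seed = 1)
  expect_identical(r$ranking, "info")
  expect_equal(nrow(r$steps), 1)
})

test_that("triplet enumeration covers every combination exactly once", {
  cs <- informative_case(6)
  blocks <- cs$blocks  # 4 candidates -> C(4,3) = 4 models
  tri <- enumerate_triplets(blocks, cs$y, seed = 1)
  expect_equal(nrow(tri$table), 4)

  oracle <- combn(names(blocks), 3, paste, collapse = "+")
  expect_setequal(tri$table$protocols, oracle)
  expect_false(anyDuplicated(tri$table$protocols) > 0)

  # 8 candidates -> 56 models
  blocks8 <- synthetic_blocks(paste0("p", 1:8), n = 40, seed = 2)
  y8 <- cs$y[1:40, ]
  tri8 <- enumerate_triplets(blocks8, y8, seed = 1)
  expect_equal(nrow(tri8$table), 56)
  expect_setequal(tri8$table$protocols,
                  combn(paste0("p", 1:8), 3, paste, collapse = "+"))

  # triplets containing the informative protocol dominate
  has_info <- grepl("info", tri$table$protocols)
  expect_gt(min(tri$table$adj_r2[has_info]),
            max(tri$table$adj_r2[!has_info]))
})

test_that("degenerate protocol blocks are dropped with a warning", {
  cs <- informative_case(7)
  blocks <- cs$blocks
  blocks$flat <- matrix(1, nrow(cs$y), 2,
                        dimnames = list(NULL, c("APD90", "CaTA")))
  expect_warning(r <- rank_protocols(blocks, cs$y, "inclusion", seed = 1),
                 "flat")
  expect_false("flat" %in% r$ranking)
})
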