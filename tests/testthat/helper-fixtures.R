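# Shared fixtures and independent oracles, built in code at test time.

# Uniform RGB image with optional disc(s) drawn on it. discs: list of
# list(row, col, radius, rgb). Returns a CapsuleImage.
discImage <- function(side = 128, bg = c(230, 228, 225), discs = list(),
                      noise = 0, seed = 1L) {
  img <- array(rep(bg, each = side * side), c(side, side, 3))
  rows <- matrix(seq_len(side), side, side)
  cols <- t(rows)
  for (d in discs) {
    m <- (rows - d$row)^2 + (cols - d$col)^2 <= d$radius^2
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m] <- d$rgb[ch]
      img[, , ch] <- plane
    }
  }
  if (noise > 0) {
    set.seed(seed)
    img <- pmin(pmax(img + stats::rnorm(length(img), sd = noise), 0), 255)
  }
  capsuleImage(img)
}

# Independent brute-force oracle for the through-origin fit: exhaustive
# 1-D grid search of the SSE over alpha in [1e-4, 1], step 1e-5.
gridSearchAlpha <- function(x, y, grid = seq(1e-4, 1, by = 1e-5)) {
  sse <- vapply(grid, function(a) sum((y - a * x)^2), numeric(1))
  grid[which.min(sse)]
}

# Independent normal-equations solution for the with-intercept line.
normalEquationsFit <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r2 = r2)
}

# Column map matching the generator's ground-truth table.
gtColumnMap <- list(sample_id = "sample_id", conc_mM = "conc_mM",
                    R_c_um = "R_c_um", h_um = "h_true_um")

# Small, fast scenario for pipeline unit tests (not the study conditions).
smallScenario <- function(seed = 11L, formationThreshold = 2) {
  scenarioSpec(concentrations = c(0.1, 2, 5, 15, 50),
               replicates = 2L, RcRange = c(300, 450),
               formationThreshold = formationThreshold,
               scale = 10, seed = seed)
}
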