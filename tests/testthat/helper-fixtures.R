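# Shared fixtures and independent oracles. Expensive fixtures are cached in
# an environment so they are built once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

# reflect padding by index folding, independent of the package internals
oracle_pad <- function(m, r) {
  fold <- function(i, n) {
    if (n == 1L) return(rep(1L, length(i)))
    p <- 2L * (n - 1L)
    j <- ((i - 1L) %% p + p) %% p
    ifelse(j < n, j + 1L, 2L * n - 1L - j)
  }
  m[fold(seq.int(1L - r, nrow(m) + r), nrow(m)),
    fold(seq.int(1L - r, ncol(m) + r), ncol(m)), drop = FALSE]
}

# brute-force sliding-window mean/variance over the disk neighborhood
oracle_mean_var <- function(g, r) {
  h <- nrow(g); w <- ncol(g)
  p <- oracle_pad(g, r)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
  M <- V <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    v <- mapply(function(dy, dx) p[i + r + dy, j + r + dx], offs$dy, offs$dx)
    M[i, j] <- mean(v)
    V[i, j] <- mean(v^2) - mean(v)^2
  }
  list(Mean = M, Var = V)
}

# direct double-loop spatial filtering
oracle_conv <- function(m, K) {
  kr <- (nrow(K) - 1L) %/% 2L
  p <- oracle_pad(m, kr)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    out[i, j] <- sum(K * p[i:(i + 2L * kr), j:(j + 2L * kr)])
  out
}

# explicit per-pixel windowed GLCM statistics (both pixels of a pair inside
# the window; symmetrized; normalized)
oracle_glcm <- function(g, r, L, offset) {
  h <- nrow(g); w <- ncol(g)
  pad <- r + 1L
  lv <- pmin(floor(pmax(pmin(g, 1), 0) * L), L - 1)
  lvp <- oracle_pad(matrix(lv, h, w), pad)
  av <- 0:(L - 1)
  res <- list(A = matrix(0, h, w), Corr = matrix(0, h, w),
              Con = matrix(0, h, w), V = matrix(0, h, w))
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ci <- i + pad; cj <- j + pad
    C <- matrix(0, L, L)
    for (qi in (ci - r):(ci + r)) for (qj in (cj - r):(cj + r)) {
      q2i <- qi + offset[1L]; q2j <- qj + offset[2L]
      if (q2i >= ci - r && q2i <= ci + r && q2j >= cj - r && q2j <= cj + r) {
        a <- lvp[qi, qj] + 1L; b <- lvp[q2i, q2j] + 1L
        C[a, b] <- C[a, b] + 1
        C[b, a] <- C[b, a] + 1
      }
    }
    P <- C / sum(C)
    mu <- sum(outer(av, av, function(a, b) a) * P)
    vv <- sum(outer(av, av, function(a, b) (a - mu)^2) * P)
    eab <- sum(outer(av, av) * P)
    res$A[i, j] <- sum(P^2)
    res$Con[i, j] <- sum(outer(av, av, function(a, b) (a - b)^2) * P)
    res$V[i, j] <- vv
    res$Corr[i, j] <- if (vv > 1e-12) (eab - mu^2) / vv else 0
  }
  res
}

# riu2 code of a circular bit pattern, written independently: count circular
# transitions; uniform patterns coded by their one-bit count, others P + 1
oracle_riu2 <- function(bits) {
  P <- length(bits)
  trans <- sum(bits != bits[c(2:P, 1L)])
  if (trans <= 2L) sum(bits) else P + 1L
}

# reference sort of combination rows
oracle_sort <- function(rows) {
  o <- order(-rows$fscore, rows$size, rows$features, method = "radix")
  rows[o, , drop = FALSE]
}

# full-table scan position vector / median
oracle_positions <- function(table, feature) {
  hits <- integer(0)
  for (i in seq_len(nrow(table))) {
    feats <- strsplit(table$features[i], ";", fixed = TRUE)[[1L]]
    if (feature %in% feats) hits <- c(hits, table$rank[i])
  }
  sort(hits)
}

# deterministic toy evaluator scoring subsets by overlap with a "good" set
toy_evaluator <- function(good) {
  function(features, seed) {
    k <- length(intersect(features, good))
    c(DV = k + 0.01 * length(features),
      CV = k - 0.01 * length(features) + 0.5)
  }
}

# a hand-built combination table from (features, fscore) pairs
make_table <- function(combos, fscores, condition = "DV") {
  rows <- data.frame(
    features = vapply(combos, function(f)
      paste(sort(f, method = "radix"), collapse = ";"), character(1L)),
    size = lengths(combos),
    fscore = fscores, stringsAsFactors = FALSE)
  tab <- sort_table(rows)
  tab$condition <- condition
  tab
}

# a linearly separable two-fold toy: one feature carries the class
toy_folds <- function(n = 60L, seed = 3L) {
  make_set <- function(sd, ids) {
    set.seed(sd)
    lab <- rep(c(0L, 2L), each = n / 2L)
    x <- cbind(sig = lab + rnorm(n, 0, 0.05), noise = rnorm(n))
    structure(list(features = x, labels = lab,
                   sample_id = rep(ids, length.out = n)),
              class = "pixel_dataset")
  }
  list(a = make_set(seed, "img_a"), b = make_set(seed + 1L, "img_b"))
}

# small synthetic dataset + pixel sets on the reduced bank (cached)
small_sets <- function() {
  cached("small_sets", function() {
    ds <- generate_dataset(synth_config(height = 48L, width = 48L),
                           4L, 4L, seed = 9L)
    bank <- reduced_bank_config()
    stacks_l <- lapply(ds$learn, function(s) build_feature_stack(s$image, bank))
    stacks_t <- lapply(ds$test, function(s) build_feature_stack(s$image, bank))
    list(
      ds = ds, bank = bank,
      a = sample_pixels(stacks_l, lapply(ds$learn, `[[`, "mask"), 300L, 7L,
                        ids = paste0("a", 1:4)),
      b = sample_pixels(stacks_t, lapply(ds$test, `[[`, "mask"), 300L, 8L,
                        ids = paste0("b", 1:4)))
  })
}

# the full two-step pipeline at the study conditions (cached); also records
# the wall-clock time of the run
acceptance_run <- function() {
  cached("acceptance_run", function() {
    t0 <- Sys.time()
    ds <- generate_dataset(synth_config(height = 64L, width = 64L),
                           10L, 10L, seed = 1L)
    cfg <- run_config(preset = "custom", bank = reduced_bank_config(),
                      n_trees = 10L, depth_grid = c(4L, 8L, 12L),
                      weight_grid = c(1, 2),
                      per_class_cap = 500L, seed = 1L)
    run <- run_pipeline(ds$learn, ds$test, cfg)
    attr(run, "elapsed_s") <-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    run
  })
}
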