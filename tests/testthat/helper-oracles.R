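# Brute-force oracles and fixture builders used across the suite.  Every
# oracle is implemented from first principles, independent of the package
# code paths it checks.

# feature_matrix from a plain numeric matrix (all-continuous schema)
make_fm <- function(v, standardise = TRUE) {
  v <- as.matrix(v)
  colnames(v) <- paste0("v", seq_len(ncol(v)))
  if (standardise) {
    ctr <- colMeans(v); spr <- apply(v, 2, stats::sd)
    v <- sweep(sweep(v, 2, ctr), 2, spr, "/")
  } else {
    ctr <- rep(0, ncol(v)); spr <- rep(1, ncol(v))
  }
  structure(list(values = v,
                 schema = data.frame(name = colnames(v), type = "continuous"),
                 scaling = list(centre = ctr, spread = spr),
                 patient_id = seq_len(nrow(v))),
            class = "feature_matrix")
}

# embedding object from raw coordinates
make_emb <- function(coords) {
  coords <- as.matrix(coords)
  structure(list(coords = coords, source = "fixture", d = ncol(coords),
                 patient_id = seq_len(nrow(coords))),
            class = "embedding")
}

# gaussian blobs around given centers; returns embedding + true labels
make_blobs <- function(n, centers, sd = 1, seed = 1) {
  set.seed(seed)
  g <- sample(nrow(centers), n, replace = TRUE)
  coords <- centers[g, , drop = FALSE] +
    matrix(rnorm(n * ncol(centers), sd = sd), n, ncol(centers))
  list(emb = make_emb(coords), labels = g)
}

# all set partitions of n elements as integer label vectors (restricted
# growth strings)
gen_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

# ARI by explicit pair counting over all element pairs
ari_oracle <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  sa <- a[pairs[1, ]] == a[pairs[2, ]]
  sb <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(sa & sb); n00 <- sum(!sa & !sb)
  n10 <- sum(sa & !sb); n01 <- sum(!sa & sb)
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)  # both partitions trivial and identical in pairs
  2 * (n11 * n00 - n10 * n01) / denom
}

# weighted Jaccard by explicit member-set enumeration
wj_oracle <- function(a, b) {
  n <- length(a)
  score <- 0
  for (ca in unique(a)) {
    A <- which(a == ca)
    best <- 0
    for (cb in unique(b)) {
      B <- which(b == cb)
      j <- length(intersect(A, B)) / length(union(A, B))
      best <- max(best, j)
    }
    score <- score + (length(A) / n) * best
  }
  score
}

# exhaustive k-means optimum: minimum within-cluster SS over all assignments
kmeans_oracle <- function(coords, k) {
  n <- nrow(coords)
  stopifnot(k^n <= 2e6)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- grid[r, ]
    w <- 0
    for (g in unique(lab)) {
      x <- coords[lab == g, , drop = FALSE]
      w <- w + sum(sweep(x, 2, colMeans(x))^2)
    }
    if (w < best) best <- w
  }
  best
}

# gap-statistic dispersion by the literal pairwise-distance formula
wk_oracle <- function(coords, labels) {
  total <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    s <- 0
    for (i in idx) for (j in idx) s <- s + sum((coords[i, ] - coords[j, ])^2)
    total <- total + s / (2 * length(idx))
  }
  total
}

# minimal patient table for prep tests
make_toy_table <- function(n = 8, seed = 1) {
  set.seed(seed)
  data.frame(
    patient_id = seq_len(n),
    trial_id = rep(c("A", "B"), length.out = n),
    arm = rep(c("bb", "placebo"), length.out = n),
    rhythm_raw = rep("SR", n),
    age = 50 + seq_len(n), bmi = 25 + runif(n), heart_rate = 70 + seq_len(n),
    sbp = 110 + seq_len(n), lvef = 25 + seq_len(n),
    creatinine = 90 + seq_len(n),
    gender = rep(c("female", "male"), length.out = n),
    prior_mi = rep(0:1, length.out = n),
    nyha = rep(1:4, length.out = n),
    acei_arb = 1, diuretic = rep(0:1, length.out = n),
    anticoagulant = 0, digoxin = rep(1:0, length.out = n),
    death = rep(0:1, length.out = n),
    followup_years = 1 + runif(n),
    stringsAsFactors = FALSE)
}

# quick small synthetic cohort, prepared
small_prepared <- function(separation = 4, n_scale = 0.05, seed = 1) {
  prepare_cohort(generate_cohort(
    default_cohort_spec(separation = separation, n_scale = n_scale,
                        seed = seed)))
}
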