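# Shared fixtures and independent oracles. Oracles are deliberately coded
# by a different route than the implementation they check.

# Regular tetrahedron with edge length `a`, one vertex at the origin.
tetrahedron_mesh <- function(a = 2) {
  v <- rbind(c(0, 0, 0),
             c(a, 0, 0),
             c(a / 2, a * sqrt(3) / 2, 0),
             c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3)))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  surface_mesh(v, f, source_label = "tetra")
}

# Independent ICC(2,1) via R's ANOVA machinery (aov), a different code path
# than the closed-form row/column sums in the implementation.
oracle_icc_2_1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(value = as.numeric(m),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(value ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Brute-force minimum distance between two infinite lines by dense sampling
# of the parameter grid (refined around the best cell).
oracle_line_distance <- function(l1, l2, span = 200, n = 2001) {
  d1 <- (l1$p2 - l1$p1) / sqrt(sum((l1$p2 - l1$p1)^2))
  d2 <- (l2$p2 - l2$p1) / sqrt(sum((l2$p2 - l2$p1)^2))
  ts <- seq(-span, span, length.out = n)
  best <- Inf
  for (t in ts) {
    q <- l1$p1 + t * d1
    w <- q - l2$p1
    # exact distance from point q to infinite line 2
    proj <- sum(w * d2)
    best <- min(best, sqrt(max(0, sum(w^2) - proj^2)))
  }
  best
}

# Brute-force closest point on a mesh by dense barycentric sampling.
oracle_snap_distance <- function(mesh, p, n = 80) {
  v <- mesh$vertices; f <- mesh$faces
  best <- Inf
  grid <- seq(0, 1, length.out = n)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    for (u in grid) for (w in grid) {
      if (u + w <= 1) {
        q <- a + u * (b - a) + w * (cc - a)
        best <- min(best, sqrt(sum((p - q)^2)))
      }
    }
  }
  best
}

# Default mandibular test pair used by several files: small arch, movements
# on a few teeth plus a scanner-pose offset.
make_test_pair <- function(global_offset = c(2, -1, 0.5),
                           global_rotation = 0,
                           bl = 0.4, vert = 0.25, rot = 7) {
  arch <- generate_arch(arch_spec("mandible"))
  mv <- movement_spec(
    per_tooth = tibble::tibble(
      tooth_id = c("LR3", "LL1", "LL2"),
      buccolingual = c(bl, 0, 0),
      vertical = c(0, vert, 0),
      rotation = c(0, 0, rot)),
    global_offset = global_offset,
    global_rotation = global_rotation)
  list(arch = arch, pair = apply_movements(arch, mv))
}

# Landmark + superpose a synthetic pair; returns T1 points in the T0 frame
# and the transform used.
superpose_pair <- function(arch, pair) {
  lm0 <- make_arch_landmark(arch$mesh, arch$guides$vertical,
                            arch$guides$horizontal, snap = FALSE,
                            arch = "mandible", timepoint = "T0")
  lm1 <- make_arch_landmark(pair$mesh_t1, pair$guides_t1$vertical,
                            pair$guides_t1$horizontal, snap = FALSE,
                            arch = "mandible", timepoint = "T1")
  sp <- superpose(pair$mesh_t1, lm1, lm0)
  list(mesh = sp$model, transform = sp$transform,
       points_t1 = apply_transform(pair$points_t1, sp$transform),
       lm0 = lm0, lm1 = lm1)
}
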