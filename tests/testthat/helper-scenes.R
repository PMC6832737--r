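# Shared fixtures for simulator-based tests: a reduced-resolution portrait
# camera (GSD ~6.6 mm at 4 m) whose footprint holds the full 5 m x 6-row
# plot, and segmentation tuned to that resolution (dilation reach ~3 cm).

test_camera <- function(H = 4) camera_model(H, 78.8, 600, 800, 0.10)

test_seg <- function(...) segmentation_params(dilation_size = 5, ...)

clean_plan <- function(seed) {
  scene_plan(spacing_sd = 0, p_missing = 0, p_double = 0,
             weed_density = 0, residue_density = 0, rng_seed = seed)
}

# brute-force optimal one-to-one matching: maximises pair count, then
# minimises total distance; independent oracle for greedy matching
bf_match_count <- function(dist, tol) {
  nd <- nrow(dist); nt <- ncol(dist)
  best <- c(0, 0)  # count, -total distance
  cand <- lapply(seq_len(nd), function(i) which(dist[i, ] <= tol))
  rec <- function(i, used, count, total) {
    if (count + (nd - i + 1) < best[1]) return()
    if (i > nd) {
      if (count > best[1] || (count == best[1] && -total > best[2]))
        best <<- c(count, -total)
      return()
    }
    for (j in cand[[i]]) if (!used[j]) {
      used[j] <- TRUE
      rec(i + 1, used, count + 1, total + dist[i, j])
      used[j] <- FALSE
    }
    rec(i + 1, used, count, total)
  }
  rec(1L, logical(nt), 0L, 0)
  best[1]
}

# stand-like random instance: truth points with >= 9 cm separation,
# detections = jittered truths with occasional misses and spurious extras
random_match_instance <- function() {
  n <- sample(2:8, 1)
  pts <- matrix(numeric(0), 0, 2)
  while (nrow(pts) < n) {
    p <- stats::runif(2)
    if (!nrow(pts) || min(sqrt(colSums((t(pts) - p)^2))) >= 0.09)
      pts <- rbind(pts, p)
  }
  truth <- data.frame(plant_id = seq_len(n), x = pts[, 1], y = pts[, 2])
  det <- truth
  det$x <- det$x + stats::rnorm(n, 0, 0.01)
  det$y <- det$y + stats::rnorm(n, 0, 0.01)
  if (stats::runif(1) < 0.3) det <- det[-sample(n, 1), , drop = FALSE]
  if (stats::runif(1) < 0.3)
    det <- rbind(det, data.frame(plant_id = n + 1, x = stats::runif(1),
                                 y = stats::runif(1)))
  names(det)[1] <- "id"
  list(truth = truth, detected = det)
}
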