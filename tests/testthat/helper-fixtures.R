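# small in-code fixtures shared across test files

# random spine-metrics table mixing all four classes
random_metrics_table <- function(n) {
  cls <- sample(SPINE_CLASSES, n, replace = TRUE)
  do.call(rbind, lapply(SPINE_CLASSES, function(c) {
    k <- sum(cls == c)
    if (k == 0) return(NULL)
    cbind(sample_geometry(c, k), true_class = c)
  }))
}

# random 3-D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random polyline as bare coordinates
random_points <- function(n) matrix(stats::runif(n * 3, -5, 5), ncol = 3)

toy_path <- function(f) system.file("extdata", f, package = "spinemorph")

# minimal classified spine table from counts per class on one segment
spines_from_counts <- function(segment_id, M = 0, LT = 0, S = 0, F = 0) {
  counts <- c(M = M, LT = LT, S = S, F = F)
  cls <- rep(names(counts), counts)
  data.frame(segment_id = rep(segment_id, sum(counts)),
             class = factor(cls, levels = SPINE_CLASSES),
             gap_flag = logical(sum(counts)), stringsAsFactors = FALSE)
}
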