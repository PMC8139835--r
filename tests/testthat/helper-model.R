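# Canonical parameter points of the E12.5 activity map (2 s pulse, 20 pA):
# single spiking, repetitive spiking, plateau.
par_ss <- function() v1r_params("basic", GNap = 0.2, GKdr = 10, I = 20)
par_rs <- function() v1r_params("basic", GNap = 1.2, GKdr = 10, I = 20)
par_pp <- function() v1r_params("basic", GNap = 1.2, GKdr = 2.5, I = 20)

# independent spike counter: local maxima above a prominence level
count_peaks <- function(V, level = -20, drop = 20) {
  n <- length(V)
  cand <- which(V[2:(n - 1)] > V[1:(n - 2)] & V[2:(n - 1)] >= V[3:n]) + 1
  cand <- cand[V[cand] > level]
  if (!length(cand)) return(0L)
  # require a trough at least `drop` mV below between successive peaks
  keep <- cand[1]
  for (i in cand[-1]) {
    prev <- keep[length(keep)]
    if (min(V[prev:i]) < min(V[prev], V[i]) - drop) keep <- c(keep, i)
  }
  length(keep)
}

# brute-force complete-linkage agglomeration: O(n^3), returns merge heights
# and the k-cluster partition
brute_complete_linkage <- function(x, k) {
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  d <- as.matrix(dist(x))
  heights <- numeric(0)
  while (length(clusters) > k) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  labels <- integer(n)
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  list(heights = heights, labels = labels)
}

# partitions equal up to label renaming
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
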