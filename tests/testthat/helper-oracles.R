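## Independent brute-force oracles: written as plainly as possible, never
## sharing code with the implementation they check.

## scalar flood fill, 8-connected; returns number of components
floodFillCount <- function(m) {
  h <- nrow(m); w <- ncol(m)
  seen <- matrix(FALSE, h, w)
  count <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!m[r0, c0] || seen[r0, c0]) next
    count <- count + 1L
    stack <- matrix(c(r0, c0), 1L, 2L)
    seen[r0, c0] <- TRUE
    while (nrow(stack)) {
      r <- stack[1, 1]; cc <- stack[1, 2]
      stack <- stack[-1, , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; ccc <- cc + dc
        if (rr >= 1 && rr <= h && ccc >= 1 && ccc <= w &&
            m[rr, ccc] && !seen[rr, ccc]) {
          seen[rr, ccc] <- TRUE
          stack <- rbind(stack, c(rr, ccc))
        }
      }
    }
  }
  count
}

## double-loop neighborhood majority with edge replication
bruteMajority <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  a <- k %/% 2
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    rr <- pmin(pmax((r - a):(r + a), 1), h)
    ccc <- pmin(pmax((cc - a):(cc + a), 1), w)
    out[r, cc] <- sum(m[rr, ccc]) * 2 > k * k
  }
  out
}

## double-loop erosion, square element anchored at floor(k/2), outside FALSE
bruteErode <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  a <- k %/% 2
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    rr <- (r - a):(r - a + k - 1)
    ccc <- (cc - a):(cc - a + k - 1)
    if (any(rr < 1) || any(rr > h) || any(ccc < 1) || any(ccc > w)) next
    out[r, cc] <- all(m[rr, ccc])
  }
  out
}

randomMask <- function(h, w, p = 0.5) {
  matrix(stats::runif(h * w) < p, h, w)
}

binMask <- function(m) new("BinaryMask", values = m)
probMask <- function(m) new("ProbabilityMask", values = m)

## small, fast fixture spec used across tests
smallSpec <- function(...) syntheticHandSpec(image_side = 400L, ...)

## set-cardinality IoU / Dice oracle over pixel index sets
setIoU <- function(a, b) {
  A <- which(a); B <- which(b)
  u <- union(A, B)
  if (!length(u)) return(1)
  length(intersect(A, B)) / length(u)
}
setDiceLoss <- function(a, b) {
  A <- which(a); B <- which(b)
  if (!length(A) && !length(B)) return(0)
  1 - 2 * length(intersect(A, B)) / (length(A) + length(B))
}
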