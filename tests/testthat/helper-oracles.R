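# Independent oracles used to check the package implementations.
# Each oracle is a deliberately simple, separately written computation:
# recursive structure enumeration for folding, quadratic scans for string
# matching. They read the same published energy tables (data, not code)
# but share no code with the package's engines.

energy_tables <- local({
  dir <- system.file("extdata", "energy", package = "lahelper")
  rd <- function(f) read.delim(file.path(dir, f), stringsAsFactors = FALSE)
  misc <- rd("misc.tsv")
  list(stack = rd("stack.tsv"), mmh = rd("mismatch_hairpin.tsv"),
       mmi = rd("mismatch_internal.tsv"), mm1n = rd("mismatch_internal_1n.tsv"),
       mm23 = rd("mismatch_internal_23.tsv"),
       hairpin = rd("hairpin_init.tsv"), bulge = rd("bulge_init.tsv"),
       internal = rd("internal_init.tsv"),
       terminal_au = misc$value[misc$key == "terminal_au"],
       ninio = misc$value[misc$key == "ninio"],
       ninio_max = misc$value[misc$key == "ninio_max"])
})

o_pair <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% c("CG", "GC", "GU", "UG", "AU", "UA")) p else NA_character_
}

o_is_au <- function(p) p %in% c("GU", "UG", "AU", "UA")

o_stack <- function(p1, p2rev) {
  t <- energy_tables$stack
  t$dg[t$pair1 == p1 & t$pair2 == p2rev]
}

o_mm <- function(tab, p, x, y) tab$dg[tab$pair == p & tab$x == x & tab$y == y]

o_loop_init <- function(tab, size) {
  if (size > 30) return(Inf)
  v <- tab$dg[tab$size == size]
  if (length(v) == 0) Inf else v
}

o_hairpin_E <- function(s, i, j) {
  p <- o_pair(s[i], s[j])
  u <- j - i - 1
  if (is.na(p) || u < 3 || u > 30) return(Inf)
  e <- o_loop_init(energy_tables$hairpin, u)
  if (u == 3) {
    e + if (o_is_au(p)) energy_tables$terminal_au else 0
  } else {
    e + o_mm(energy_tables$mmh, p, s[i + 1], s[j - 1])
  }
}

o_interior_E <- function(s, i, j, k, l) {
  p1 <- o_pair(s[i], s[j])
  p2r <- o_pair(s[l], s[k])
  if (is.na(p1) || is.na(p2r)) return(Inf)
  u1 <- k - i - 1
  u2 <- j - l - 1
  aup <- function(p) if (o_is_au(p)) energy_tables$terminal_au else 0
  if (u1 == 0 && u2 == 0) return(o_stack(p1, p2r))
  if (u1 == 0 || u2 == 0) {
    b <- u1 + u2
    if (b > 30) return(Inf)
    if (b == 1) return(o_loop_init(energy_tables$bulge, 1) + o_stack(p1, p2r))
    return(o_loop_init(energy_tables$bulge, b) + aup(p1) + aup(p2r))
  }
  n <- u1 + u2
  if (n > 30) return(Inf)
  tab <- if (min(u1, u2) == 1) energy_tables$mm1n
         else if (min(u1, u2) == 2 && max(u1, u2) == 3) energy_tables$mm23
         else energy_tables$mmi
  o_loop_init(energy_tables$internal, n) +
    min(energy_tables$ninio * abs(u1 - u2), energy_tables$ninio_max) +
    o_mm(tab, p1, s[i + 1], s[j - 1]) + o_mm(tab, p2r, s[l + 1], s[k - 1])
}

# best energy of a hairpin closed by (i, j), by plain recursive enumeration
o_closed_min <- function(s, i, j) {
  if (is.na(o_pair(s[i], s[j]))) return(Inf)
  best <- o_hairpin_E(s, i, j)
  if (j - i >= 6) {
    for (k in (i + 1):(j - 5)) {
      if (k - i - 1 > 30) break
      for (l in (k + 4):(j - 1)) {
        if (j - l - 1 > 30) next
        inner <- o_closed_min(s, k, l)
        if (is.finite(inner)) {
          best <- min(best, o_interior_E(s, i, j, k, l) + inner)
        }
      }
    }
  }
  best
}

# all closed-hairpin energies (terminal AU penalty included), as a data frame
oracle_fold_all <- function(seq) {
  s <- strsplit(chartr("Tt", "UU", toupper(seq)), "")[[1]]
  n <- length(s)
  out <- NULL
  for (i in seq_len(n - 4)) {
    for (j in (i + 4):n) {
      p <- o_pair(s[i], s[j])
      if (is.na(p)) next
      e <- o_closed_min(s, i, j)
      if (is.finite(e)) {
        e <- e + if (o_is_au(p)) energy_tables$terminal_au else 0
        out <- rbind(out, data.frame(i = i, j = j, e = e))
      }
    }
  }
  out
}

oracle_mfe <- function(seq) {
  all <- oracle_fold_all(seq)
  if (is.null(all) || min(all$e) >= 0) return(NULL)
  min(all$e)
}

# quadratic maximal-exact-match oracle; positions relative to each string
oracle_mems <- function(query, subject, min_len, q_off = 0L, s_off = 0L,
                        require_disjoint = TRUE) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  nq <- length(q); ns <- length(s)
  hits <- NULL
  for (i in seq_len(nq)) {
    for (j in seq_len(ns)) {
      left_open <- i == 1 || j == 1 || q[i - 1] != s[j - 1]
      if (!left_open || q[i] != s[j]) next
      len <- 0L
      while (i + len <= nq && j + len <= ns && q[i + len] == s[j + len] &&
               q[i + len] != "N") len <- len + 1L
      if (len < min_len) next
      qa <- i + q_off; qe <- i + len - 1L + q_off
      sa <- j + s_off; se <- j + len - 1L + s_off
      if (require_disjoint && qa <= se && sa <= qe) next
      hits <- rbind(hits, data.frame(q_start = qa, q_end = qe,
                                     s_start = sa, s_end = se, length = len))
    }
  }
  if (is.null(hits)) return(NULL)
  hits <- unique(hits)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    for (j in seq_len(nrow(hits))) {
      if (i != j &&
            hits$q_start[j] <= hits$q_start[i] &&
            hits$q_end[j] >= hits$q_end[i] &&
            hits$s_start[j] <= hits$s_start[i] &&
            hits$s_end[j] >= hits$s_end[i] &&
            hits$length[j] > hits$length[i]) keep[i] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits[order(-hits$length, hits$q_start), , drop = FALSE]
}

# palindrome oracle: direct enumeration over (loop position, loop size)
oracle_palindromes <- function(seq, min_arm = 8L, max_loop = 8L,
                               max_mismatch = 2L) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  rc <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  hits <- NULL
  for (g in 0:max_loop) {
    for (c0 in seq_len(n - g)) {
      amax <- min(c0 - 1L, n - c0 - g + 1L)
      best_a <- 0L; best_m <- 0L
      if (amax >= 1L) {
        mism <- cumsum(rc[s[c0 - seq_len(amax)]] != s[c0 + g - 1L + seq_len(amax)])
        ok <- which(mism <= max_mismatch &
                      rc[s[c0 - seq_len(amax)]] == s[c0 + g - 1L + seq_len(amax)])
        if (length(ok) > 0 && max(ok) >= min_arm) {
          best_a <- max(ok); best_m <- mism[best_a]
        }
      }
      if (best_a >= min_arm) {
        hits <- rbind(hits, data.frame(start = c0 - best_a, end = c0 + g - 1L + best_a,
                                       arm_len = best_a, loop_len = g,
                                       mismatches = best_m))
      }
    }
  }
  if (is.null(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      arm_len = integer(0), loop_len = integer(0),
                      mismatches = integer(0)))
  }
  hits <- unique(hits)
  ord <- order(-(hits$end - hits$start), -hits$arm_len, hits$start)
  hits <- hits[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    inside <- hits$start >= hits$start[i] & hits$end <= hits$end[i] &
      (hits$end - hits$start < hits$end[i] - hits$start[i] |
         hits$arm_len < hits$arm_len[i])
    inside[i] <- FALSE
    keep[inside] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits[order(hits$start, hits$end), , drop = FALSE]
}

# brute-force slippery heptamer scan, character by character
oracle_slippery <- function(seq, strict = TRUE) {
  s <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  out <- integer(0)
  for (i in seq_len(length(s) - 6L)) {
    h <- s[i:(i + 6L)]
    if (h[1] == h[2] && h[2] == h[3] && h[4] == h[5] && h[5] == h[6] &&
          !any(h %in% "N")) {
      if (!strict || (h[4] %in% c("A", "T") && h[7] != "G")) {
        out <- c(out, i)
      }
    }
  }
  out
}
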