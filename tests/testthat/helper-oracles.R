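# Independent brute-force oracles and random-profile generators.
# These deliberately re-derive each rule with straightforward code that
# shares nothing with the package implementations.

# ---- random ASCN profiles ---------------------------------------------------

# one sample: every chromosome cut into 1..max_segs contiguous pieces with
# random allele-specific states
random_ascn_profile <- function(genome, sample_id = "S1", max_segs = 8,
                                states = list(c(1, 1), c(1, 0), c(2, 1),
                                              c(2, 0), c(2, 2), c(3, 1),
                                              c(0, 0))) {
  rows <- list()
  for (i in seq_len(nrow(genome))) {
    L <- genome$length[i]
    k <- sample(1:max_segs, 1)
    cuts <- sort(sample(seq(2, L - 1), k - 1))
    starts <- c(1, cuts)
    ends <- c(cuts - 1, L)
    for (j in seq_len(k)) {
      st <- states[[sample(length(states), 1)]]
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sample_id, chrom = genome$chrom[i],
        start_bp = starts[j], end_bp = ends[j],
        total_cn = st[1] + st[2], major_cn = st[1], minor_cn = st[2])
    }
  }
  segment_table(do.call(rbind, rows), allele_specific = TRUE, genome = genome)
}

# split random segments at random points, preserving states
refragment <- function(segments, n_cuts = 10) {
  df <- as.data.frame(segments)
  for (k in seq_len(n_cuts)) {
    i <- sample(nrow(df), 1)
    if (df$end_bp[i] - df$start_bp[i] < 2) next
    cut <- sample(seq(df$start_bp[i] + 1, df$end_bp[i]), 1)
    new <- df[i, ]
    new$start_bp <- cut
    df$end_bp[i] <- cut - 1
    df <- rbind(df, new)
  }
  segment_table(df, allele_specific = "major_cn" %in% names(df))
}

# ---- scar-score oracles (literal rule implementations) ----------------------

# maximal runs of segments satisfying pred, one chromosome at a time
.oracle_runs <- function(d, pred) {
  d <- d[order(d$chrom, d$start_bp), ]
  out <- list()
  for (ch in unique(d$chrom)) {
    dc <- d[d$chrom == ch, ]
    ok <- pred(dc)
    grp <- cumsum(c(TRUE, diff(ok) != 0 |
                      dc$start_bp[-1] - dc$end_bp[-nrow(dc)] - 1 > 1))
    for (g in split(seq_len(nrow(dc)), grp)) {
      if (!ok[g[1]]) next
      out[[length(out) + 1]] <- list(chrom = ch,
                                     start = dc$start_bp[g[1]],
                                     end = dc$end_bp[g[length(g)]])
    }
  }
  out
}

oracle_loh <- function(segments, genome, min_len = 15e6) {
  sapply(sort(unique(segments$sample_id)), function(s) {
    d <- segments[segments$sample_id == s, ]
    runs <- .oracle_runs(d, function(dc) dc$minor_cn == 0 & dc$total_cn >= 1)
    n <- 0
    for (r in runs) {
      dc <- d[d$chrom == r$chrom, ]
      covered <- max(dc$end_bp) - min(dc$start_bp) + 1
      len <- r$end - r$start + 1
      if (len > min_len && len < covered) n <- n + 1
    }
    n
  })
}

oracle_tai <- function(segments, genome, min_len = 0, slack = 0) {
  sapply(sort(unique(segments$sample_id)), function(s) {
    d <- segments[segments$sample_id == s, ]
    runs <- .oracle_runs(d, function(dc) dc$major_cn != dc$minor_cn)
    n <- 0
    for (r in runs) {
      dc <- d[d$chrom == r$chrom, ]
      gi <- which(genome$chrom == r$chrom)
      at_start <- r$start <= min(dc$start_bp) + slack
      at_end <- r$end >= max(dc$end_bp) - slack
      crosses <- r$start < genome$cen_start[gi] && r$end > genome$cen_end[gi]
      if ((at_start || at_end) && !crosses &&
          (r$end - r$start + 1) >= min_len) n <- n + 1
    }
    n
  })
}

oracle_lst <- function(segments, genome, min_seg = 10e6, max_gap = 3e6,
                       smooth_below = 3e6) {
  sapply(sort(unique(segments$sample_id)), function(s) {
    d <- segments[segments$sample_id == s, ]
    total <- 0
    for (ch in unique(d$chrom)) {
      gi <- which(genome$chrom == ch)
      mid <- floor((genome$cen_start[gi] + genome$cen_end[gi]) / 2)
      dc <- d[d$chrom == ch, ]
      dc <- dc[order(dc$start_bp), ]
      # split at the centromere midpoint
      pieces <- list()
      for (i in seq_len(nrow(dc))) {
        if (dc$start_bp[i] <= mid && dc$end_bp[i] > mid) {
          a <- dc[i, ]; a$end_bp <- mid
          b <- dc[i, ]; b$start_bp <- mid + 1
          pieces <- c(pieces, list(a, b))
        } else pieces <- c(pieces, list(dc[i, ]))
      }
      dc <- do.call(rbind, pieces)
      dc$arm <- ifelse(dc$end_bp <= mid, "p", "q")
      for (arm in c("p", "q")) {
        a <- dc[dc$arm == arm, ]
        if (nrow(a) == 0) next
        a <- a[order(a$start_bp), ]
        # smooth: drop smallest < smooth_below, extend larger neighbour;
        # merge identical adjacent states first each round
        repeat {
          i <- 1
          while (i < nrow(a)) {
            if (a$major_cn[i] == a$major_cn[i + 1] &&
                a$minor_cn[i] == a$minor_cn[i + 1] &&
                a$start_bp[i + 1] - a$end_bp[i] - 1 <= max_gap) {
              a$end_bp[i] <- a$end_bp[i + 1]
              a <- a[-(i + 1), ]
            } else i <- i + 1
          }
          len <- a$end_bp - a$start_bp + 1
          sm <- which(len < smooth_below)
          if (length(sm) == 0 || nrow(a) == 1) break
          k <- sm[which.min(len[sm])]
          ll <- if (k > 1) len[k - 1] else -1
          rl <- if (k < nrow(a)) len[k + 1] else -1
          if (ll >= rl) a$end_bp[k - 1] <- a$end_bp[k]
          else a$start_bp[k + 1] <- a$start_bp[k]
          a <- a[-k, ]
        }
        if (nrow(a) < 2) next
        len <- a$end_bp - a$start_bp + 1
        for (i in seq_len(nrow(a) - 1)) {
          if ((a$major_cn[i] != a$major_cn[i + 1] ||
               a$minor_cn[i] != a$minor_cn[i + 1]) &&
              len[i] >= min_seg && len[i + 1] >= min_seg &&
              a$start_bp[i + 1] - a$end_bp[i] - 1 <= max_gap)
            total <- total + 1
        }
      }
    }
    total
  })
}

# ---- other oracles ----------------------------------------------------------

# pairwise O(n^2) ROC AUC
oracle_roc <- function(p, y) {
  pos <- p[y == "positive"]; neg <- p[y == "negative"]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# explicit threshold-sweep PR area (same step convention, separate code)
oracle_pr <- function(p, y) {
  pos <- sum(y == "positive")
  ths <- sort(unique(p), decreasing = TRUE)
  prev_r <- 0; area <- 0
  for (t in ths) {
    tp <- sum(p >= t & y == "positive")
    fp <- sum(p >= t & y == "negative")
    r <- tp / pos; pr <- tp / (tp + fp)
    area <- area + (r - prev_r) * pr
    prev_r <- r
  }
  area
}

# brute-force best F1 over every distinct calling pattern
oracle_best_f1 <- function(p, y) {
  cands <- sort(unique(c(0, p, 1)))
  best <- 0
  for (t in cands) {
    call <- p >= t
    tp <- sum(call & y == "positive")
    fp <- sum(call & y == "negative")
    fn <- sum(!call & y == "positive")
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    best <- max(best, f1)
  }
  best
}

# pairwise merge scan to fixpoint (total-CN tables)
oracle_merge <- function(segments, tol = 0.1, gap_max = 1) {
  df <- as.data.frame(segments)
  repeat {
    df <- df[order(df$sample_id, df$chrom, df$start_bp), ]
    done <- TRUE
    for (i in seq_len(nrow(df) - 1)) {
      if (df$sample_id[i] == df$sample_id[i + 1] &&
          df$chrom[i] == df$chrom[i + 1] &&
          df$start_bp[i + 1] - df$end_bp[i] - 1 <= gap_max &&
          abs(df$total_cn[i] - df$total_cn[i + 1]) <= tol) {
        l1 <- df$end_bp[i] - df$start_bp[i] + 1
        l2 <- df$end_bp[i + 1] - df$start_bp[i + 1] + 1
        df$total_cn[i] <- (df$total_cn[i] * l1 + df$total_cn[i + 1] * l2) / (l1 + l2)
        df$end_bp[i] <- df$end_bp[i + 1]
        df <- df[-(i + 1), ]
        done <- FALSE
        break
      }
    }
    if (done) return(segment_table(df))
  }
}

# small helper: a plain total-CN table from vectors on one chromosome
cn_profile <- function(cn, lens_mb, chrom = "1", sample_id = "S1", start = 1) {
  ends <- start - 1 + cumsum(lens_mb * 1e6)
  starts <- c(start, utils::head(ends, -1) + 1)
  segment_table(data.frame(sample_id = sample_id, chrom = chrom,
                           start_bp = starts, end_bp = ends, total_cn = cn))
}
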