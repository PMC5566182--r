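# Interval-score CNV detection over per-probe log2 ratios.
#
# Two scoring tiers share one statistic, the error-normalised interval
# score S(I) = |sum_k u_k| / sqrt(|I|):
#   * global ("ADM-1-like"):  u_k = r_k / sigma_hat  with a single robust
#     array noise estimate sigma_hat (DLRS);
#   * weighted ("ADM-2-like"): u_k = r_k / sigma_k with per-probe errors.
# Calls come from a recursive maximal-interval search per chromosome.

#' Caller configuration
#'
#' @param threshold_t minimum interval score for a call (default 6.0, a
#'   conventional aberration-detection default; exposed here and reported
#'   in output metadata).
#' @param min_probes minimum probes per call (default 3, the usual
#'   multi-probe reporting convention).
#' @param max_interval_probes cap on interval length during the search.
#' @param gain_cut,loss_cut mean centered log2 cutoffs for typing a
#'   significant interval as gain/loss (defaults +0.30/-0.30, midway
#'   between noise and the heterozygous amplitudes +0.58/-1).
#' @param centering `"mode"` or `"median"`, see [center_signal()].
#' @return list of class `caller_config`.
#' @export
caller_config <- function(threshold_t = 6, min_probes = 3,
                          max_interval_probes = 10000,
                          gain_cut = 0.30, loss_cut = -0.30,
                          centering = c("mode", "median")) {
  stopifnot(threshold_t > 0, min_probes >= 1)
  structure(list(threshold_t = threshold_t,
                 min_probes = as.integer(min_probes),
                 max_interval_probes = as.integer(max_interval_probes),
                 gain_cut = gain_cut, loss_cut = loss_cut,
                 centering = match.arg(centering)),
            class = "caller_config")
}

#' Centralise a signal table
#'
#' Shifts log2 ratios so the dominant (diploid) state sits at zero. The
#' `"mode"` method locates the highest peak of a Gaussian kernel density
#' estimate of the ratios (ties resolved toward zero) and refines it to
#' the mean of the probes within 2 MAD of that peak — a raw histogram or
#' KDE mode alone is too noisy to localise the flat-topped diploid peak,
#' while the clipped mean around it is efficient and still ignores
#' aberrant segments. `"median"` subtracts the median. The returned table
#' carries the offset in the `"centering_offset"` attribute and is flagged
#' `"centered"`.
#'
#' @param signals a `probe_signals` table with >= 10 probes.
#' @param method `"mode"` (default) or `"median"`.
#' @return the centered signal table with attributes `centered` (TRUE),
#'   `centering_offset`, and `zero_spread` (TRUE when all input values were
#'   identical).
#' @export
center_signal <- function(signals, method = c("mode", "median")) {
  method <- match.arg(method)
  r <- signals$log2_ratio
  if (length(r) < 10) stop("center_signal: need at least 10 probes")
  zero_spread <- length(unique(r)) == 1L
  offset <- if (zero_spread) {
    r[1]
  } else if (method == "median") {
    stats::median(r)
  } else {
    d <- stats::density(r, n = 2048)
    top <- which(d$y == max(d$y))
    peak <- d$x[top[which.min(abs(d$x[top]))]]
    s <- stats::mad(r)
    near <- abs(r - peak) <= 2 * s
    if (any(near)) mean(r[near]) else peak
  }
  signals$log2_ratio <- r - offset
  attr(signals, "centered") <- TRUE
  attr(signals, "centering_offset") <- offset
  attr(signals, "zero_spread") <- zero_spread
  if (zero_spread) warning("center_signal: zero spread in input signal")
  signals
}

#' Derivative log-ratio spread (DLRS)
#'
#' Robust array noise estimate from successive probe differences:
#' `1.4826 * median(|r[i+1] - r[i]|) / sqrt(2)` within each chromosome,
#' pooled across chromosomes by the median. Insensitive to true CNV
#' segments, which contribute only two breakpoint differences each.
#'
#' @param signals a `probe_signals` table ordered by genome position
#'   (at least 2 probes on some chromosome).
#' @return estimated probe noise SD (log2 units).
#' @export
dlrs <- function(signals) {
  if (nrow(signals) < 2) stop("dlrs: need at least 2 probes")
  signals <- sort_by_position(signals)
  per_chrom <- vapply(split(signals$log2_ratio, signals$chrom), function(r) {
    if (length(r) < 2) return(NA_real_)
    1.4826 * stats::median(abs(diff(r))) / sqrt(2)
  }, 0)
  per_chrom <- per_chrom[!is.na(per_chrom)]
  if (!length(per_chrom)) stop("dlrs: no chromosome with >= 2 probes")
  stats::median(per_chrom)
}

#' Interval score of a probe run
#'
#' @param signals a `probe_signals` table (position-sorted within the
#'   chromosome of interest).
#' @param i,j 1-based first and last probe index, `i <= j`.
#' @param mode `"global"` (one shared noise estimate) or `"weighted"`
#'   (per-probe errors). With `sigma_k = sigma_hat` for all probes the two
#'   modes coincide.
#' @param sigma_hat global noise SD (required for `"global"`).
#' @return the interval score `S = |sum(u)| / sqrt(j - i + 1)`.
#' @export
score_interval <- function(signals, i, j, mode = c("global", "weighted"),
                           sigma_hat = NULL) {
  mode <- match.arg(mode)
  stopifnot(i >= 1, j >= i, j <= nrow(signals))
  r <- signals$log2_ratio[i:j]
  if (mode == "global") {
    if (is.null(sigma_hat) || sigma_hat <= 0) {
      stop("score_interval: global mode needs sigma_hat > 0")
    }
    u <- r / sigma_hat
  } else {
    sk <- signals$probe_error[i:j]
    if (any(!is.finite(sk) | sk <= 0)) {
      stop("score_interval: per-probe errors must be positive")
    }
    u <- r / sk
  }
  abs(sum(u)) / sqrt(length(u))
}

# Highest-scoring contiguous interval of u within [lo, hi], considering
# lengths min_probes..max_len. Ties: higher score, then longer, then
# leftmost. Returns NULL when no admissible interval exists.
#' @noRd
best_interval <- function(u, lo, hi, min_probes, max_len) {
  n <- hi - lo + 1
  if (n < min_probes) return(NULL)
  useg <- u[lo:hi]
  cs <- c(0, cumsum(useg))
  best <- NULL
  for (L in seq(min_probes, min(n, max_len))) {
    s <- abs(cs[(L + 1):(n + 1)] - cs[1:(n - L + 1)]) / sqrt(L)
    k <- which.max(s)
    if (is.null(best) || s[k] > best$score + 1e-12 ||
        (abs(s[k] - best$score) <= 1e-12 && L > best$len)) {
      best <- list(i = lo + k - 1, j = lo + k - 1 + L - 1,
                   score = s[k], len = L)
    }
  }
  best
}

#' Detect aberrant intervals in a centered signal
#'
#' Per chromosome, finds the highest-scoring contiguous probe interval
#' (exhaustively over all start/length pairs up to `max_interval_probes`,
#' with at least `min_probes` probes); if its score reaches `threshold_t`
#' the interval is emitted and the search recurses independently on the
#' left and right flanks. Score ties break longest-then-leftmost.
#' Significant intervals whose mean log2 ratio reaches neither `gain_cut`
#' nor `loss_cut` are discarded (but their flanks are still searched).
#'
#' @param signals a centered `probe_signals` table (see [center_signal()]).
#' @param config a [caller_config()].
#' @param mode `"global"` (ADM-1-like) or `"weighted"` (ADM-2-like).
#' @param sigma_hat global noise SD; computed by [dlrs()] when missing.
#' @return a [cnv_calls()] table; calls within one mode never overlap.
#' @export
find_aberrations <- function(signals, config = caller_config(),
                             mode = c("global", "weighted"),
                             sigma_hat = NULL) {
  mode <- match.arg(mode)
  if (!isTRUE(attr(signals, "centered"))) {
    stop("find_aberrations: signals must be centered first",
         " (see center_signal)")
  }
  if (is.null(sigma_hat)) sigma_hat <- dlrs(signals)
  if (sigma_hat <= 0) stop("find_aberrations: sigma_hat must be > 0")
  signals <- sort_by_position(signals)
  algo <- if (mode == "global") "ADM1-like" else "ADM2-like"
  rows <- list()
  for (chr in unique(signals$chrom)) {
    sub <- signals[signals$chrom == chr, , drop = FALSE]
    u <- if (mode == "global") {
      sub$log2_ratio / sigma_hat
    } else {
      if (any(!is.finite(sub$probe_error) | sub$probe_error <= 0)) {
        stop("find_aberrations: per-probe errors must be positive")
      }
      sub$log2_ratio / sub$probe_error
    }
    stack <- list(c(1, nrow(sub)))
    while (length(stack)) {
      seg <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      b <- best_interval(u, seg[1], seg[2], config$min_probes,
                         config$max_interval_probes)
      if (is.null(b) || b$score < config$threshold_t) next
      m <- mean(sub$log2_ratio[b$i:b$j])
      if (m >= config$gain_cut || m <= config$loss_cut) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chr, start = sub$start[b$i], stop = sub$stop[b$j],
          cnv_type = if (m > 0) "gain" else "loss",
          n_probes = b$j - b$i + 1, mean_log2 = m, score = b$score,
          stringsAsFactors = FALSE)
      }
      if (b$i - seg[1] >= config$min_probes) {
        stack[[length(stack) + 1]] <- c(seg[1], b$i - 1)
      }
      if (seg[2] - b$j >= config$min_probes) {
        stack[[length(stack) + 1]] <- c(b$j + 1, seg[2])
      }
    }
  }
  if (!length(rows)) return(cnv_calls(assembly = interval_assembly(signals)))
  df <- do.call(rbind, rows)
  cnv_calls(df$chrom, df$start, df$stop, df$cnv_type, df$n_probes,
            df$mean_log2, df$score, algorithms = algo,
            tier = "single-algorithm",
            cn_estimate = estimate_copy_number(df$mean_log2),
            assembly = interval_assembly(signals))
}

#' Integrate call sets from the two scoring tiers
#'
#' Calls from the global-noise and probe-error-weighted analyses of the
#' same array are matched by reciprocal overlap (>= `min_reciprocal_overlap`
#' of both lengths) on the same chromosome with the same type. Matched
#' pairs merge into one call (union interval, maximum score, union of
#' algorithm labels) with tier `"both"`; unmatched calls are retained with
#' tier `"single-algorithm"` — a weighted-only or global-only call can be a
#' real variant, so neither list filters the other.
#'
#' @param calls_a,calls_b two [cnv_calls()] tables from the same signals.
#' @param min_reciprocal_overlap default 0.5.
#' @return integrated [cnv_calls()] table, sorted; never longer than the
#'   two inputs combined.
#' @export
integrate_calls <- function(calls_a, calls_b, min_reciprocal_overlap = 0.5) {
  if (nrow(calls_a) == 0 && nrow(calls_b) == 0) return(calls_a)
  used_b <- rep(FALSE, nrow(calls_b))
  rows <- list()
  for (i in seq_len(nrow(calls_a))) {
    cand <- which(!used_b & calls_b$chrom == calls_a$chrom[i] &
                    calls_b$cnv_type == calls_a$cnv_type[i])
    match_j <- NA_integer_
    best_ov <- 0
    for (j in cand) {
      ov <- max(0, min(calls_a$stop[i], calls_b$stop[j]) -
                  max(calls_a$start[i], calls_b$start[j]))
      if (ov / (calls_a$stop[i] - calls_a$start[i]) >=
          min_reciprocal_overlap &&
          ov / (calls_b$stop[j] - calls_b$start[j]) >=
          min_reciprocal_overlap && ov > best_ov) {
        best_ov <- ov
        match_j <- j
      }
    }
    if (!is.na(match_j)) {
      used_b[match_j] <- TRUE
      j <- match_j
      lead <- if (calls_a$score[i] >= calls_b$score[j]) calls_a[i, ] else
        calls_b[j, ]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = calls_a$chrom[i],
        start = min(calls_a$start[i], calls_b$start[j]),
        stop = max(calls_a$stop[i], calls_b$stop[j]),
        cnv_type = calls_a$cnv_type[i],
        n_probes = max(calls_a$n_probes[i], calls_b$n_probes[j]),
        mean_log2 = lead$mean_log2,
        score = max(calls_a$score[i], calls_b$score[j]),
        algorithms = paste(sort(unique(c(
          strsplit(calls_a$algorithms[i], ",")[[1]],
          strsplit(calls_b$algorithms[j], ",")[[1]]))), collapse = ","),
        tier = "both", stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = calls_a$chrom[i], start = calls_a$start[i],
        stop = calls_a$stop[i], cnv_type = calls_a$cnv_type[i],
        n_probes = calls_a$n_probes[i], mean_log2 = calls_a$mean_log2[i],
        score = calls_a$score[i], algorithms = calls_a$algorithms[i],
        tier = "single-algorithm", stringsAsFactors = FALSE)
    }
  }
  for (j in which(!used_b)) {
    rows[[length(rows) + 1]] <- data.frame(
      chrom = calls_b$chrom[j], start = calls_b$start[j],
      stop = calls_b$stop[j], cnv_type = calls_b$cnv_type[j],
      n_probes = calls_b$n_probes[j], mean_log2 = calls_b$mean_log2[j],
      score = calls_b$score[j], algorithms = calls_b$algorithms[j],
      tier = "single-algorithm", stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  cnv_calls(df$chrom, df$start, df$stop, df$cnv_type, df$n_probes,
            df$mean_log2, df$score, df$algorithms, df$tier,
            cn_estimate = estimate_copy_number(df$mean_log2),
            assembly = interval_assembly(calls_a))
}
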