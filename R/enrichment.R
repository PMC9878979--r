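# Signed rank scores and a preranked gene-set enrichment engine: weighted
# Kolmogorov-Smirnov running-sum statistic, gene-permutation null,
# sign-pooled FDR q values.

#' Compute signed rank scores from differential-expression results
#'
#' Each feature gets the score `sign(log2fc) * (-log2(p_raw))`: strongly
#' up-regulated features rank at the top, strongly down-regulated at the
#' bottom. Features are optionally mapped to gene symbols via a two-column
#' map; duplicate genes keep the entry with the largest absolute score. Zero
#' p values are clamped to one tenth of the smallest positive p value and
#' flagged in the `clamped` attribute.
#'
#' @param de data.frame with `feature`, `log2fc`, `p_raw`.
#' @param gene_map optional data.frame (feature/protein id, gene symbol);
#'   unmapped features are dropped with a count in the `unmapped` attribute.
#' @return data.frame `gene`, `score` sorted by descending score, ties broken
#'   lexicographically by gene.
#' @export
compute_rank_scores <- function(de, gene_map = NULL) {
  if (is.null(de) || nrow(de) == 0) stop("empty differential-expression input")
  p <- de$p_raw
  clamped <- character(0)
  if (any(!is.na(p) & p == 0)) {
    floor_p <- min(p[!is.na(p) & p > 0]) / 10
    if (!is.finite(floor_p)) stop("all p values are zero; cannot form scores")
    clamped <- de$feature[!is.na(p) & p == 0]
    p[!is.na(p) & p == 0] <- floor_p
  }
  score <- sign(de$log2fc) * (-log2(p))
  gene <- de$feature
  unmapped <- 0L
  if (!is.null(gene_map)) {
    idx <- match(de$feature, gene_map[[1]])
    unmapped <- sum(is.na(idx))
    keep <- !is.na(idx)
    gene <- gene_map[[2]][idx[keep]]
    score <- score[keep]
  }
  keep <- !is.na(score) & is.finite(score)
  gene <- gene[keep]; score <- score[keep]
  # duplicates keep the best |score|
  o <- order(-abs(score))
  gene <- gene[o]; score <- score[o]
  first <- !duplicated(gene)
  gene <- gene[first]; score <- score[first]
  o <- order(-score, gene)
  out <- data.frame(gene = gene[o], score = score[o], stringsAsFactors = FALSE)
  attr(out, "clamped") <- clamped
  attr(out, "unmapped") <- unmapped
  out
}

# ES from sorted hit positions: the running sum increments by the hit's
# weight share at each hit and decreases linearly between hits, so the signed
# extremum is attained just after or just before a hit.
es_from_positions <- function(pos, w_abs, N) {
  k <- length(pos)
  wh <- w_abs[pos]
  sw <- sum(wh)
  cw <- if (sw > 0) cumsum(wh) / sw else cumsum(rep(1 / k, k))
  miss <- (pos - seq_len(k)) / (N - k)
  top <- cw - miss                 # just after each hit
  bottom <- c(0, cw[-k]) - miss    # just before each hit
  hi <- max(top, 0)
  lo <- min(bottom, 0)
  # exact magnitude ties (possible at rational step sizes) resolve positive
  if (hi >= -lo - 1e-9) hi else lo
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list; genes in the set increment the running sum by
#' `|score|^weight / sum_set |score|^weight`, genes outside decrement it by
#' `1 / (N - N_set)`. The enrichment score is the signed maximum-magnitude
#' deviation of the running sum from zero (ties favour the positive side).
#'
#' @param ranked data.frame `gene`, `score`, descending (from
#'   [compute_rank_scores()]).
#' @param set character vector of gene symbols.
#' @param weight exponent on `|score|` (1 = classical weighted scheme,
#'   0 = unweighted Kolmogorov-Smirnov).
#' @return list with `es` and `running` (the full running-sum vector).
#' @export
enrichment_score <- function(ranked, set, weight = 1) {
  N <- nrow(ranked)
  hit <- ranked$gene %in% set
  k <- sum(hit)
  if (k == 0) stop("gene set does not intersect the ranked list")
  if (k == N) stop("gene set covers the entire ranked list")
  w <- abs(ranked$score)^weight
  sw <- sum(w[hit])
  step <- if (sw > 0) ifelse(hit, w / sw, -1 / (N - k))
          else ifelse(hit, 1 / k, -1 / (N - k))
  running <- cumsum(step)
  es <- es_from_positions(which(hit), w, N)
  list(es = es, running = running)
}

#' Preranked gene-set enrichment with gene-permutation FDR
#'
#' For every set, computes the weighted running-sum enrichment score and a
#' null distribution of scores from `n_perm` random gene sets of the same
#' size. The normalized enrichment score (NES) divides the observed score by
#' the mean magnitude of same-sign null scores; the nominal p value is the
#' one-sided fraction of same-sign null scores at least as extreme; the FDR q
#' value pools null and observed NES within each sign class (the classical
#' preranked scheme) and is made monotone in |NES|. Sets are selected at
#' `q <= 0.05` (non-strict).
#'
#' @param ranked data.frame `gene`, `score`, descending.
#' @param sets named list of gene-symbol vectors (see [read_gmt()]).
#' @param n_perm number of gene permutations (>= 100).
#' @param seed integer seed.
#' @param weight running-sum weight (see [enrichment_score()]).
#' @param q_select selection threshold on the q value.
#' @return data.frame: `set`, `size`, `es`, `nes`, `p_nominal`, `q_fdr`,
#'   `selected`.
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000L, seed = 1L,
                           weight = 1, q_select = 0.05) {
  stopifnot(n_perm >= 100)
  N <- nrow(ranked)
  w <- abs(ranked$score)^weight
  sizes <- vapply(sets, function(s) sum(ranked$gene %in% s), integer(1))
  if (any(sizes == 0)) stop("gene set(s) with no overlap: ",
                            paste(names(sets)[sizes == 0], collapse = ", "))
  if (any(sizes >= N)) stop("gene set larger than the ranked list")
  es_obs <- vapply(names(sets), function(nm) {
    enrichment_score(ranked, sets[[nm]], weight)$es
  }, numeric(1))
  with_seed(seed, {
    null_es <- lapply(seq_along(sets), function(i) {
      k <- sizes[i]
      vapply(seq_len(n_perm), function(b) {
        es_from_positions(sort(sample.int(N, k)), w, N)
      }, numeric(1))
    })
    nes_of <- function(es, null) {
      mp <- mean(null[null > 0]); mn <- mean(abs(null[null < 0]))
      ifelse(es >= 0,
             if (is.finite(mp) && mp > 0) es / mp else NA_real_,
             if (is.finite(mn) && mn > 0) es / mn else NA_real_)
    }
    nes_obs <- mapply(nes_of, es_obs, null_es)
    null_nes <- unlist(lapply(seq_along(sets), function(i) {
      vapply(null_es[[i]], nes_of, numeric(1), null = null_es[[i]])
    }), use.names = FALSE)
    p_nom <- mapply(function(es, null) {
      same <- null[sign(null) == sign(es) | es == 0]
      if (length(same) == 0) return(1 / (n_perm + 1))
      (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    }, es_obs, null_es)

    q <- rep(NA_real_, length(sets))
    for (sgn in c(1, -1)) {
      io <- which(sign(nes_obs) == sgn)
      if (!length(io)) next
      np <- null_nes[sign(null_nes) == sgn & !is.na(null_nes)]
      for (i in io) {
        num <- if (length(np)) mean(abs(np) >= abs(nes_obs[i])) else 0
        den <- mean(abs(nes_obs[io]) >= abs(nes_obs[i]))
        q[i] <- min(1, num / den)
      }
      # enforce q monotone non-increasing in |NES| within the sign class:
      # walking from the strongest set down, q can only grow
      o <- order(abs(nes_obs[io]), decreasing = TRUE)
      q[io][o] <- cummax(q[io][o])
    }
    q[!is.na(nes_obs) & nes_obs == 0] <- 1
    data.frame(set = names(sets), size = unname(sizes), es = unname(es_obs),
               nes = unname(nes_obs), p_nominal = unname(p_nom),
               q_fdr = q, selected = !is.na(q) & q <= q_select,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}
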