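# Motif discovery and scanning: short NB-domain motifs found by ZOOPS
# (zero-or-one occurrence per sequence) expectation-maximisation with
# sequential erasure, scored on proteins with exact staged-convolution
# p-values and a product-of-p-values (QFAST) combined significance.

code_seqs <- function(seqs) {
  lapply(seqs, function(s) {
    idx <- match(strsplit(s, "")[[1]], AA20)
    idx  # NA marks unknown residues and erased (masked) sites
  })
}

seq_background <- function(coded) {
  tab <- tabulate(unlist(coded), nbins = 20L)
  if (sum(tab) == 0) abort("no standard residues in motif input")
  bg <- tab / sum(tab)
  names(bg) <- AA20
  bg
}

valid_windows <- function(x, w) {
  n <- length(x)
  if (n < w) return(integer(0))
  ok <- !is.na(x)
  cs <- c(0L, cumsum(ok))
  starts <- seq_len(n - w + 1L)
  starts[(cs[starts + w] - cs[starts]) == w]
}

# ZOOPS EM for one width. Deterministic: initialised from the most frequent
# exact w-mer over the unmasked windows (ties: rarest composition under the
# background, then lexicographic order).
zoops_em <- function(coded, w, bg, max_iter = 50L, tol = 1e-4,
                     pseudo_frac = 0.01) {
  wins <- lapply(coded, valid_windows, w = w)
  nwin <- lengths(wins)
  use <- which(nwin > 0)
  if (length(use) < 2) return(NULL)

  wmers <- unlist(lapply(use, function(s) {
    vapply(wins[[s]], function(j)
      paste(AA20[coded[[s]][j:(j + w - 1L)]], collapse = ""), "")
  }))
  tab <- table(wmers)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) {
    rarity <- vapply(top, function(m)
      sum(-log(bg[strsplit(m, "")[[1]]])), 0)
    top <- top[rarity == max(rarity)]
    top <- sort(top)[1]
  }
  seed_idx <- match(strsplit(top, "")[[1]], AA20)
  beta <- 0.3
  theta <- matrix(rep(bg, each = w), nrow = w)
  theta <- beta * theta
  theta[cbind(seq_len(w), seed_idx)] <- theta[cbind(seq_len(w), seed_idx)] + (1 - beta)
  gamma <- 0.5

  pc <- pseudo_frac * bg  # per-cell background pseudocounts
  ll_old <- -Inf
  z_list <- NULL
  for (iter in seq_len(max_iter)) {
    logtheta <- log(theta)
    logbg <- log(bg)
    c_mat <- matrix(rep(pc, each = w), nrow = w)
    z_list <- vector("list", length(coded))
    ztot <- numeric(length(coded))
    ll <- 0
    for (s in use) {
      x <- coded[[s]]
      js <- wins[[s]]
      llr <- vapply(js, function(j) {
        ix <- x[j:(j + w - 1L)]
        sum(logtheta[cbind(seq_len(w), ix)] - logbg[ix])
      }, 0)
      lr <- exp(llr)
      prior <- gamma / length(js)
      denom <- (1 - gamma) + prior * sum(lr)
      z <- prior * lr / denom
      z_list[[s]] <- setNames(z, js)
      ztot[s] <- sum(z)
      ll <- ll + log(denom)  # log-likelihood ratio vs background-only
      for (k in seq_along(js)) {
        if (z[k] > 1e-9) {
          ix <- x[js[k]:(js[k] + w - 1L)]
          c_mat[cbind(seq_len(w), ix)] <- c_mat[cbind(seq_len(w), ix)] + z[k]
        }
      }
    }
    theta <- c_mat / rowSums(c_mat)
    gamma <- min(0.99, max(0.01, mean(ztot[use])))
    if (abs(ll - ll_old) < tol) { ll_old <- ll; break }
    ll_old <- ll
  }

  # hard site assignment for reporting and erasure
  sites <- tibble(seq = integer(), pos = integer())
  for (s in use) {
    z <- z_list[[s]]
    if (length(z) && max(z) > 0.5) {
      sites <- bind_rows(sites, tibble(seq = s, pos = as.integer(names(z)[which.max(z)])))
    }
  }
  list(width = w, llr = ll_old, sites = sites, gamma = gamma)
}

motif_from_sites <- function(coded, sites, w, bg, id, pseudo_frac = 0.01) {
  nsites <- nrow(sites)
  pc <- pseudo_frac * bg
  counts <- matrix(rep(pc, each = w), nrow = w,
                   dimnames = list(NULL, AA20))
  for (r in seq_len(nsites)) {
    ix <- coded[[sites$seq[r]]][sites$pos[r]:(sites$pos[r] + w - 1L)]
    counts[cbind(seq_len(w), ix)] <- counts[cbind(seq_len(w), ix)] + 1
  }
  freq <- counts / rowSums(counts)
  logodds <- log2(sweep(freq, 2, bg, "/"))
  # residues absent from the background (zero frequency) get a finite floor
  # so scores and the null convolution stay well defined
  logodds[!is.finite(logodds)] <- -20
  consensus <- paste(AA20[apply(freq, 1, which.max)], collapse = "")
  out <- list(id = id, width = w, counts = counts, logodds = logodds,
              background = bg, nsites = nsites, consensus = consensus,
              sites = sites)
  out$score_dist <- motif_score_dist(out)  # cached null distribution
  out
}

#' Discover protein motifs by ZOOPS EM with sequential erasure
#'
#' Motifs are discovered one at a time: for each motif, a zero-or-one
#' occurrence-per-sequence EM is run at every width in `[min_w, max_w]`, the
#' width with the best BIC-penalized total log-likelihood ratio is kept (the
#' raw ratio always grows with width, so each column pays
#' `0.5 * 19 * log(nsites)`), and the accepted motif's sites are erased
#' before the next round. Runs are deterministic for
#' fixed inputs: initialisation is from the most frequent exact w-mer.
#'
#' @param seqs Character vector of protein sequences (>= 2, each at least
#'   `max_w` long).
#' @param n_motifs Maximum number of motifs (default 19).
#' @param min_w,max_w Width bounds (defaults 4 and 7).
#' @param seed Accepted for interface stability; the algorithm is
#'   deterministic and does not consume randomness.
#' @return List of motif models (`id`, `width`, `counts`, `logodds`,
#'   `background`, `nsites`, `consensus`, `sites`).
#' @export
discover_motifs <- function(seqs, n_motifs = 19L, min_w = 4L, max_w = 7L,
                            seed = 1L) {
  if (length(seqs) < 2) abort("motif discovery needs at least 2 sequences")
  if (any(nchar(seqs) < max_w)) abort("all sequences must be at least max_w long")
  coded <- code_seqs(seqs)
  bg <- seq_background(coded)
  if (sum(bg > 0) < 2) abort("degenerate input: single-residue composition")
  motifs <- list()
  for (m in seq_len(n_motifs)) {
    fits <- lapply(seq.int(min_w, max_w), function(w) zoops_em(coded, w, bg))
    fits <- fits[!vapply(fits, is.null, TRUE)]
    fits <- fits[vapply(fits, function(f) nrow(f$sites) >= 2, TRUE)]
    if (length(fits) == 0) break
    # width selection by BIC-penalized log-likelihood ratio: the raw LLR
    # grows with every extra column (a random flank still fits noise), so
    # each column pays 0.5 * 19 * log(nsites)
    crit <- vapply(fits, function(f)
      f$llr - 0.5 * 19 * f$width * log(max(nrow(f$sites), 2)), 0)
    best <- fits[[which.max(crit)]]
    if (best$llr <= 0) break
    motifs[[m]] <- motif_from_sites(coded, best$sites, best$width, bg, id = m)
    # erase the accepted sites
    for (r in seq_len(nrow(best$sites))) {
      s <- best$sites$seq[r]; p <- best$sites$pos[r]
      coded[[s]][p:(p + best$width - 1L)] <- NA
    }
  }
  motifs
}

# Integer-rescaled (centibit) per-position score distributions; staged
# convolution gives the exact null distribution of the window score.
motif_score_dist <- function(motif, precision = 100) {
  si <- round(motif$logodds * precision)
  bg <- motif$background
  w <- motif$width
  cur <- c(1)          # distribution over offset scores
  cur_lo <- 0
  for (i in seq_len(w)) {
    row <- si[i, ]
    rlo <- min(row); rhi <- max(row)
    new <- numeric(length(cur) + rhi - rlo)
    for (a in seq_len(20)) {
      sh <- row[a] - rlo
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + cur * bg[a]
    }
    cur <- new
    cur_lo <- cur_lo + rlo
  }
  list(probs = cur, min_score = cur_lo, int_matrix = si, precision = precision)
}

#' Scan a protein with a motif and report exact p-values for every window
#'
#' Window scores are summed integer-rescaled log-odds (resolution 1/100 bit);
#' the p-value of a score is the exact tail probability of the staged
#' convolution of the per-position score distributions under the motif's
#' background.
#'
#' @param protein Protein string (length >= motif width).
#' @param motif A motif model from [discover_motifs()].
#' @param protein_id Identifier recorded in the output.
#' @return Tibble with `motif`, `protein_id`, `pos` (1-based), `score` (bits)
#'   and `pvalue`, one row per window.
#' @export
motif_hit_pvalue <- function(protein, motif, protein_id = NA_character_) {
  dist <- motif$score_dist %||% motif_score_dist(motif)
  si <- dist$int_matrix
  w <- motif$width
  idx <- match(strsplit(protein, "")[[1]], AA20)
  n <- length(idx)
  if (n < w) {
    return(tibble(motif = integer(), protein_id = character(),
                  pos = integer(), score = numeric(), pvalue = numeric()))
  }
  nw <- n - w + 1L
  sc <- integer(nw)
  ok <- rep(TRUE, nw)
  for (i in seq_len(w)) {
    col <- idx[seq.int(i, i + nw - 1L)]
    ok <- ok & !is.na(col)
    v <- unname(si[i, ifelse(is.na(col), 1L, col)])
    sc <- sc + v
  }
  # exact upper-tail CDF over integer scores
  tail_prob <- rev(cumsum(rev(dist$probs)))
  pos_of <- function(s) pmin(pmax(s - dist$min_score + 1L, 1L), length(tail_prob))
  pv <- ifelse(sc < dist$min_score, 1,
               ifelse(sc > dist$min_score + length(tail_prob) - 1L, 0,
                      tail_prob[pos_of(sc)]))
  out <- tibble(motif = motif$id, protein_id = protein_id,
                pos = seq_len(nw), score = sc / dist$precision,
                pvalue = pmin(pmax(pv, .Machine$double.xmin), 1))
  out[ok, ]
}

#' Combine per-motif p-values into a QFAST combined p-value and E-value
#'
#' For best p-values \eqn{p_1..p_n}, the product \eqn{q = \prod p_i} gives the
#' combined p-value \eqn{q \sum_{k=0}^{n-1} (-\ln q)^k / k!}; the E-value
#' scales it by the database size.
#'
#' @param pvalues Numeric vector of per-motif best p-values, each in (0, 1].
#' @param n_db Database size (number of proteins searched).
#' @return List with `combined_p` and `evalue`.
#' @export
combined_evalue <- function(pvalues, n_db) {
  if (any(pvalues <= 0)) abort("p-values must be > 0")
  if (any(pvalues > 1)) abort("p-values must be <= 1")
  n <- length(pvalues)
  logq <- sum(log(pvalues))
  # q * sum_{k<n} (-log q)^k / k!, computed in log space for stability
  terms <- cumsum(c(0, log(pmax(-logq, .Machine$double.xmin)) -
                      log(seq_len(max(n - 1, 0)))))
  combined <- sum(exp(logq + terms[seq_len(n)]))
  combined <- min(combined, 1)
  list(combined_p = combined, evalue = combined * n_db)
}

#' Serialize motifs in MEME minimal text format
#'
#' @param motifs List of motif models.
#' @param path Output path.
#' @export
write_meme <- function(motifs, path) {
  if (length(motifs) == 0) {
    writeLines("MEME version 4", path)
    return(invisible(path))
  }
  bg <- motifs[[1]]$background
  lines <- c("MEME version 4", "", "ALPHABET= ACDEFGHIKLMNPQRSTVWY", "",
             "Background letter frequencies", paste(
               paste(names(bg), sprintf("%.5f", bg)), collapse = " "), "")
  for (m in motifs) {
    freq <- m$counts / rowSums(m$counts)
    ord <- match(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], AA20)
    lines <- c(lines,
               sprintf("MOTIF M%02d %s", m$id, m$consensus),
               sprintf("letter-probability matrix: alength= 20 w= %d nsites= %d E= 0",
                       m$width, m$nsites),
               apply(freq[, ord, drop = FALSE], 1, function(r)
                 paste(sprintf("%.6f", r), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}
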