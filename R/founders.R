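#' Expected founder contributions to a reference population
#'
#' Propagates each reference animal's genome backward through the pedigree,
#' halving at every parent link. Mass reaching a founder (both parents
#' unknown) accumulates into that founder's expected contribution `p_i`;
#' mass reaching an unknown parent of a non-founder accumulates into a
#' phantom residual, so `sum(p) + residual = 1`.
#'
#' @param ped a `pedigree`.
#' @param reference subset selector (default `"reference"`).
#' @return list of class `founder_contributions` with `p` (named over
#'   founders, in pedigree order), `residual` (phantom mass) and
#'   `reference_size`.
#' @examples
#' founder_contributions(make_toy("full_sib_mating"))$p  # A = B = 0.5
#' @export
founder_contributions <- function(ped, reference = "reference") {
  stopifnot(inherits(ped, "pedigree"))
  ref <- resolve_subset(ped, reference)
  if (!length(ref)) stop("reference population is empty")
  par <- ped_parents(ped)
  n <- nrow(ped)
  w <- numeric(n)
  w[ref] <- w[ref] + 1 / length(ref)
  residual <- 0
  fo <- is_founder(ped)
  for (i in n:1) {
    if (w[i] == 0 || fo[i]) next
    half <- w[i] / 2
    if (par$sire[i] > 0L) w[par$sire[i]] <- w[par$sire[i]] + half else residual <- residual + half
    if (par$dam[i] > 0L) w[par$dam[i]] <- w[par$dam[i]] + half else residual <- residual + half
    w[i] <- 0
  }
  structure(list(p = stats::setNames(w[fo], ped$id[fo]),
                 residual = residual, reference_size = length(ref)),
            class = "founder_contributions")
}

#' Effective number of founders
#'
#' `f_e = 1 / sum(p_i^2)`: the number of equally contributing founders that
#' would produce the observed founder-contribution inequality. By default
#' the contribution vector is renormalized over true founders (phantom
#' residual excluded); set `include_phantoms = FALSE` off to keep the raw
#' scale.
#'
#' @param p a [founder_contributions()] object or a bare numeric vector of
#'   contributions.
#' @param renormalize divide by `1 - residual` before squaring (only
#'   meaningful for `founder_contributions` input).
#' @return scalar f_e.
#' @export
effective_founders <- function(p, renormalize = TRUE) {
  v <- if (inherits(p, "founder_contributions")) p$p else as.numeric(p)
  if (all(v == 0)) stop("all founder contributions are zero")
  if (renormalize && inherits(p, "founder_contributions") && p$residual < 1) {
    v <- v / (1 - p$residual)
  } else {
    v <- v / sum(v)
  }
  1 / sum(v^2)
}

# transmit founder alleles down the pedigree; one column per replicate.
# Founder k carries alleles 2k-1, 2k; an unknown parent of a non-founder
# contributes a unique negative allele per slot (constant across replicates:
# identity, not identity-by-descent, is what matters for uniqueness).
drop_alleles <- function(ped, replicates) {
  par <- ped_parents(ped)
  n <- nrow(ped)
  fo <- is_founder(ped)
  frank <- cumsum(fo)
  a1 <- matrix(0L, n, replicates)
  a2 <- matrix(0L, n, replicates)
  for (i in seq_len(n)) {
    if (fo[i]) {
      a1[i, ] <- 2L * frank[i] - 1L
      a2[i, ] <- 2L * frank[i]
      next
    }
    s <- par$sire[i]; d <- par$dam[i]
    if (s > 0L) {
      pick <- stats::runif(replicates) < 0.5
      a1[i, ] <- ifelse(pick, a1[s, ], a2[s, ])
    } else a1[i, ] <- -(2L * i - 1L)
    if (d > 0L) {
      pick <- stats::runif(replicates) < 0.5
      a2[i, ] <- ifelse(pick, a1[d, ], a2[d, ])
    } else a2[i, ] <- -(2L * i)
  }
  list(a1 = a1, a2 = a2, founder_rows = which(fo))
}

#' Gene-drop estimate of founder allele retention
#'
#' Monte-Carlo gene dropping: every replicate assigns two unique alleles to
#' each founder, transmits one allele uniformly at random from each parent
#' down the ordered pedigree, and scores, per founder, the fraction of its
#' two alleles still present among the reference animals (0, 1/2 or 1).
#' `r_i` is the mean over replicates: the expected proportion of founder
#' i's genome preserved in the reference population.
#'
#' @param ped a `pedigree`.
#' @param reference subset selector (default `"reference"`).
#' @param replicates Monte-Carlo replicates (default 10,000).
#' @param seed integer seed; identical seeds give identical estimates.
#' @return list of class `gene_drop_result` with `r` (named per founder),
#'   `se` (Monte-Carlo standard errors), `replicates` and `seed`.
#' @export
gene_drop <- function(ped, reference = "reference", replicates = 10000L,
                      seed = 1L) {
  stopifnot(inherits(ped, "pedigree"), replicates >= 1L)
  ref <- resolve_subset(ped, reference)
  if (!length(ref)) stop("reference population is empty")
  set.seed(seed)
  dr <- drop_alleles(ped, replicates)
  refA <- rbind(dr$a1[ref, , drop = FALSE], dr$a2[ref, , drop = FALSE])
  nf <- length(dr$founder_rows)
  r <- numeric(nf)
  se <- numeric(nf)
  for (k in seq_len(nf)) {
    kept <- (colSums(refA == 2L * k - 1L) > 0) + (colSums(refA == 2L * k) > 0)
    frac <- kept / 2
    r[k] <- mean(frac)
    se[k] <- stats::sd(frac) / sqrt(replicates)
  }
  ids <- ped$id[dr$founder_rows]
  structure(list(r = stats::setNames(r, ids), se = stats::setNames(se, ids),
                 replicates = replicates, seed = seed),
            class = "gene_drop_result")
}

#' Founder genome equivalent
#'
#' `f_ge = 1 / sum(p_i^2 / r_i)` over founders with `p_i > 0`: the number of
#' equally contributing founders, with no allele loss, that would give the
#' observed diversity. Since `r_i <= 1`, always `f_ge <= f_e`.
#'
#' @param p a [founder_contributions()] object (renormalized over true
#'   founders) or numeric vector.
#' @param r a [gene_drop_result()] or numeric vector aligned with `p`.
#' @param renormalize as in [effective_founders()].
#' @return scalar f_ge.
#' @export
founder_genome_equivalent <- function(p, r, renormalize = TRUE) {
  v <- if (inherits(p, "founder_contributions")) p$p else as.numeric(p)
  rv <- if (inherits(r, "gene_drop_result")) r$r else as.numeric(r)
  if (inherits(p, "founder_contributions") && inherits(r, "gene_drop_result")) {
    rv <- rv[names(v)]
  }
  stopifnot(length(v) == length(rv))
  if (renormalize && inherits(p, "founder_contributions") && p$residual < 1) {
    v <- v / (1 - p$residual)
  }
  use <- v > 0
  if (any(use & (is.na(rv) | rv == 0))) {
    stop("founder with positive contribution but zero retention: inconsistent inputs")
  }
  1 / sum(v[use]^2 / rv[use])
}

#' Effective number of non-founders
#'
#' `N_enf = (1/f_ge - 1/f_e)^-1`: isolates the diversity lost by genetic
#' drift and bottlenecks in the non-founder generations. Equal `f_e` and
#' `f_ge` (no drift loss) give `Inf`.
#'
#' @param f_e effective number of founders.
#' @param f_ge founder genome equivalent (must not exceed `f_e`).
#' @return scalar N_enf (possibly `Inf`).
#' @examples
#' non_founder_equivalent(152, 53)  # 81.4, printed as 81
#' @export
non_founder_equivalent <- function(f_e, f_ge) {
  stopifnot(f_ge > 0, f_e > 0)
  if (f_ge > f_e + 1e-12) stop("f_ge exceeds f_e: inconsistent inputs")
  if (abs(1 / f_ge - 1 / f_e) < 1e-15) return(Inf)
  1 / (1 / f_ge - 1 / f_e)
}

#' Expected-heterozygosity style diversity measures
#'
#' `GD = 1 - 1/(2 f_ge)` accounts for unequal founder contributions plus
#' drift and bottlenecks; `GD* = 1 - 1/(2 f_e)` for founder inequality only.
#' The report also partitions the total loss `1 - GD` into the founder
#' component `1 - GD*` and the drift/bottleneck component
#' `GD* - GD = 1/(2 N_enf)`.
#'
#' @param f_e effective number of founders (>= 0.5).
#' @param f_ge founder genome equivalent (>= 0.5).
#' @return list of class `diversity_report` with `f_e`, `f_ge`, `N_enf`,
#'   `GD`, `GD_star`, `loss_total`, `loss_founder`, `loss_drift`.
#' @examples
#' genetic_diversity(f_e = 87, f_ge = 18)$loss_founder * 100  # 0.57%
#' @export
genetic_diversity <- function(f_e, f_ge) {
  stopifnot(f_e >= 0.5, f_ge >= 0.5)
  GD <- 1 - 1 / (2 * f_ge)
  GD_star <- 1 - 1 / (2 * f_e)
  structure(list(
    f_e = f_e, f_ge = f_ge,
    N_enf = non_founder_equivalent(f_e, f_ge),
    GD = GD, GD_star = GD_star,
    loss_total = 1 - GD,
    loss_founder = 1 - GD_star,
    loss_drift = GD_star - GD
  ), class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf(
    paste0("Genetic diversity: f_e = %.1f, f_ge = %.1f, N_enf = %.1f\n",
           "  GD = %.5f  GD* = %.5f\n",
           "  loss: total %.3f%%  founder %.3f%%  drift/bottleneck %.3f%%\n"),
    x$f_e, x$f_ge, x$N_enf, x$GD, x$GD_star,
    100 * x$loss_total, 100 * x$loss_founder, 100 * x$loss_drift))
  invisible(x)
}

#' Founder decomposition of the mean inbreeding coefficient
#'
#' Partitions each reference animal's inbreeding coefficient by the founder
#' from which the identical-by-descent allele pair descends:
#' `F_i = sum_j F_i^(j)` over founders j (plus phantom unknown-parent
#' sources, reported as a residual). The per-founder share of the group mean
#' is `vf_j = 100 * mean_i F_i^(j) / mean_i F_i`, the percentage of the mean
#' inbreeding attributable to founder j.
#'
#' The `exact_recursive` method evaluates a founder-partitioned kinship
#' recursion that mirrors the standard kinship recursion: for a founder f,
#' the partitioned self-kinship is 1/2 toward f and 0 toward every other
#' source; for a non-founder a, the partitioned self-kinship toward source j
#' is `(p_j(a) + phi_j(sire_a, dam_a)) / 2` where `p_j(a)` is source j's
#' genetic contribution to a. The `gene_drop` method estimates the same
#' partition by Monte-Carlo IBD tracing of founder alleles.
#'
#' @param ped a `pedigree`.
#' @param reference subset selector (default `"reference"`).
#' @param method `"exact_recursive"` or `"gene_drop"`.
#' @param replicates Monte-Carlo replicates for `gene_drop`.
#' @param seed seed for `gene_drop`.
#' @return list of class `inbreeding_decomposition` with `mean_F`, `table`
#'   (founder id, contribution `p`, `F_share` = mean partitioned F, `vf`
#'   percent, ranked), `residual_vf` (phantom percentage), per-animal
#'   partition matrix `F_partition` (reference animals x sources) and
#'   diagnostics `v` (founder contributions), `m` (Mendelian sampling
#'   variances) and `u` (expected genetic contribution of every ancestor to
#'   the reference).
#' @export
inbreeding_decomposition <- function(ped, reference = "reference",
                                     method = c("exact_recursive", "gene_drop"),
                                     replicates = 10000L, seed = 1L) {
  stopifnot(inherits(ped, "pedigree"))
  method <- match.arg(method)
  ref <- resolve_subset(ped, reference)
  if (!length(ref)) stop("reference population is empty")
  par <- ped_parents(ped)
  n <- nrow(ped)
  fo <- is_founder(ped)
  nf <- sum(fo)

  # source coordinates: true founders first, then one phantom per unknown
  # parent slot of a non-founder
  frank <- cumsum(fo)
  ph_s <- which(!fo & par$sire == 0L)
  ph_d <- which(!fo & par$dam == 0L)
  K <- nf + length(ph_s) + length(ph_d)
  ph_s_coord <- if (length(ph_s)) nf + seq_along(ph_s) else integer(0)
  ph_d_coord <- if (length(ph_d)) nf + length(ph_s) + seq_along(ph_d) else integer(0)
  slot_s <- integer(n); slot_s[ph_s] <- ph_s_coord
  slot_d <- integer(n); slot_d[ph_d] <- ph_d_coord

  # per-animal source contribution matrix C (n x K), rows sum to 1
  C <- matrix(0, n, K)
  for (i in seq_len(n)) {
    if (fo[i]) { C[i, frank[i]] <- 1; next }
    if (par$sire[i] > 0L) C[i, ] <- C[i, ] + 0.5 * C[par$sire[i], ]
    else C[i, slot_s[i]] <- C[i, slot_s[i]] + 0.5
    if (par$dam[i] > 0L) C[i, ] <- C[i, ] + 0.5 * C[par$dam[i], ]
    else C[i, slot_d[i]] <- C[i, slot_d[i]] + 0.5
  }

  Fall <- inbreeding_coefficients(ped)$F
  FP <- matrix(0, length(ref), K,
               dimnames = list(ped$id[ref], NULL))

  if (method == "exact_recursive") {
    memo <- new.env(parent = emptyenv(), size = 4L * n)
    phi <- function(a, b) {
      if (a == 0L || b == 0L) return(numeric(K))
      if (a > b) { tmp <- a; a <- b; b <- tmp }
      key <- paste0(a, ":", b)
      hit <- memo[[key]]
      if (!is.null(hit)) return(hit)
      val <- if (a == b) {
        if (fo[a]) {
          e <- numeric(K); e[frank[a]] <- 0.5; e
        } else {
          (C[a, ] + phi(par$sire[a], par$dam[a])) / 2
        }
      } else {
        (phi(a, par$sire[b]) + phi(a, par$dam[b])) / 2
      }
      assign(key, val, envir = memo)
      val
    }
    for (k in seq_along(ref)) {
      i <- ref[k]
      if (par$sire[i] > 0L && par$dam[i] > 0L) {
        FP[k, ] <- phi(par$sire[i], par$dam[i])
      }
    }
  } else {
    set.seed(seed)
    dr <- drop_alleles(ped, replicates)
    for (k in seq_along(ref)) {
      i <- ref[k]
      x <- dr$a1[i, ]; y <- dr$a2[i, ]
      ibd <- x == y
      if (!any(ibd)) next
      al <- x[ibd]
      coord <- ifelse(al > 0L, (al + 1L) %/% 2L,
                      ifelse(-al %% 2L == 1L, slot_s[(-al + 1L) %/% 2L],
                             slot_d[-al %/% 2L]))
      tab <- table(coord)
      FP[k, as.integer(names(tab))] <- as.numeric(tab) / replicates
    }
  }

  mean_F <- mean(Fall[ref])
  mean_part <- colMeans(FP)
  founder_ids <- ped$id[fo]
  if (mean_F == 0) {
    vf <- rep(NA_real_, nf)
    residual_vf <- NA_real_
  } else {
    vf <- 100 * mean_part[seq_len(nf)] / mean_F
    residual_vf <- 100 * sum(mean_part[-seq_len(nf)]) / mean_F
    if (K == nf) residual_vf <- 0
  }

  pc <- founder_contributions(ped, reference = ref)
  tab <- data.frame(founder = founder_ids,
                    p = as.numeric(pc$p[founder_ids]),
                    F_share = mean_part[seq_len(nf)],
                    vf = vf, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$F_share, tab$founder), , drop = FALSE]
  rownames(tab) <- NULL

  # diagnostics: v = founder gene contributions, m = Mendelian sampling
  # variances, u = expected contribution of every ancestor to the reference
  m <- mendelian_variance(ped, Fall)
  u <- ancestor_contributions(ped, ref)
  structure(list(mean_F = mean_F, table = tab, residual_vf = residual_vf,
                 F_partition = FP, method = method,
                 replicates = if (method == "gene_drop") replicates else NA_integer_,
                 seed = if (method == "gene_drop") seed else NA_integer_,
                 v = pc$p, m = m, u = u),
            class = "inbreeding_decomposition")
}

# Mendelian sampling variance of each animal given parental inbreeding
mendelian_variance <- function(ped, F = inbreeding_coefficients(ped)$F) {
  par <- ped_parents(ped)
  s <- par$sire; d <- par$dam
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], NA_real_)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], NA_real_)
  D <- ifelse(s == 0L & d == 0L, 1,
              ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (Fs + Fd),
                     0.75 - 0.25 * ifelse(s > 0L, Fs, Fd)))
  stats::setNames(as.numeric(D), ped$id)
}

# expected genetic contribution of every animal (not only founders) to the
# mean reference genome: backward propagation without stopping at founders
ancestor_contributions <- function(ped, ref) {
  par <- ped_parents(ped)
  n <- nrow(ped)
  w <- numeric(n)
  w[ref] <- 1 / length(ref)
  acc <- w
  for (i in n:1) {
    if (w[i] == 0) next
    half <- w[i] / 2
    if (par$sire[i] > 0L) {
      w[par$sire[i]] <- w[par$sire[i]] + half
      acc[par$sire[i]] <- acc[par$sire[i]] + half
    }
    if (par$dam[i] > 0L) {
      w[par$dam[i]] <- w[par$dam[i]] + half
      acc[par$dam[i]] <- acc[par$dam[i]] + half
    }
  }
  stats::setNames(acc, ped$id)
}

#' @export
print.inbreeding_decomposition <- function(x, ...) {
  cat(sprintf("Founder decomposition of mean F = %.5f (%s)\n",
              x$mean_F, x$method))
  top <- utils::head(x$table, 10L)
  print(transform(top, vf = round(vf, 2), p = round(p, 4),
                  F_share = signif(F_share, 4)), row.names = FALSE)
  if (!is.na(x$residual_vf) && x$residual_vf > 0) {
    cat(sprintf("phantom (unknown-parent) share: %.2f%%\n", x$residual_vf))
  }
  invisible(x)
}
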