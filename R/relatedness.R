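#' Individual inbreeding coefficients (Meuwissen-Luo)
#'
#' Computes F for every animal by the Meuwissen & Luo ancestor-tracing
#' algorithm on the topologically ordered pedigree. F equals the
#' corresponding diagonal element of the numerator relationship matrix minus
#' one, but the algorithm never materializes that matrix, so pedigrees well
#' beyond 10,000 animals are handled in linear memory.
#'
#' @param ped a `pedigree` (parent-first order, as returned by [pedigree()]).
#' @return list of class `inbreeding_result` with `F` (named numeric),
#'   `is_inbred` (`F > 0`) and `pct_inbred` (percent of animals with F > 0).
#' @examples
#' inbreeding_coefficients(make_toy("full_sib_mating"))$F[["E"]]  # 0.25
#' @export
inbreeding_coefficients <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  par <- ped_parents(ped)
  if (any(par$sire >= seq_len(nrow(ped)) & par$sire > 0L) ||
      any(par$dam >= seq_len(nrow(ped)) & par$dam > 0L)) {
    stop("pedigree is not topologically ordered; call topological_order() first")
  }
  F <- .ml_inbreeding(par$sire, par$dam)
  names(F) <- ped$id
  structure(list(F = F, is_inbred = F > 0,
                 pct_inbred = 100 * mean(F > 0)),
            class = "inbreeding_result")
}

#' @export
print.inbreeding_result <- function(x, ...) {
  cat(sprintf("Inbreeding: n = %d, mean F = %.4f%%, inbred = %.1f%%\n",
              length(x$F), 100 * mean(x$F), x$pct_inbred))
  invisible(x)
}

#' Individual increase in inbreeding
#'
#' Per-generation rate of inbreeding implied by an individual's F given its
#' pedigree depth in equivalent complete generations t:
#' `dF = 1 - (1 - F)^(1/(t - 1))`. Each animal's own t is used, so animals
#' with shallow recorded pedigrees are not understated relative to animals
#' with deep ones. For `t <= 1` the rate is 0 when F = 0 and undefined
#' (`NaN`) otherwise.
#'
#' @param F_i inbreeding coefficient(s) in `[0, 1]`.
#' @param t_i equivalent complete generations of the same animal(s).
#' @return numeric vector of per-generation rates.
#' @export
delta_F <- function(F_i, t_i) {
  if (any(F_i < 0 | F_i > 1, na.rm = TRUE)) {
    stop("F must lie in [0, 1]")
  }
  stopifnot(length(F_i) == length(t_i))
  out <- ifelse(t_i > 1, 1 - (1 - F_i)^(1 / (t_i - 1)),
                ifelse(F_i == 0, 0, NaN))
  names(out) <- names(F_i)
  out
}

#' Realized effective population size from individual rates
#'
#' `Ne = 1 / (2 * mean(dF))` on the proportion scale, the size of an
#' idealized population losing heterozygosity at the observed mean rate.
#' Undefined rates (`NaN`) are dropped; a zero mean rate gives `Inf`.
#'
#' @param dF individual increases in inbreeding (proportion scale).
#' @return scalar Ne (possibly `Inf`).
#' @examples
#' effective_population_size(0.00220)  # 227.3, printed as 227
#' @export
effective_population_size <- function(dF) {
  dF <- dF[!is.na(dF)]
  if (!length(dF)) stop("no usable rates in group")
  m <- mean(dF)
  if (m < 0) stop("mean rate of inbreeding is negative")
  if (m == 0) return(Inf)
  1 / (2 * m)
}

#' Pairwise kinship (coancestry) by memoized recursion
#'
#' Kinship f(a, b) is the probability that one allele drawn from each animal
#' is identical by descent; the numerator relationship is 2f. Evaluation
#' recurses on the pair member appearing later in the topological order
#' (which guarantees termination) and caches every evaluated pair, so group
#' means are computed without materializing the full relationship matrix.
#'
#' @param ped a `pedigree`.
#' @param a,b animal ids or row indices.
#' @param cache optional environment reused across calls for memoization.
#' @return kinship coefficient(s).
#' @export
kinship <- function(ped, a, b, cache = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  ia <- resolve_subset(ped, a)
  ib <- resolve_subset(ped, b)
  stopifnot(length(ia) == length(ib))
  if (is.null(cache)) cache <- new_kinship_cache(ped)
  vapply(seq_along(ia), function(k) kin_pair(cache, ia[k], ib[k]), numeric(1))
}

new_kinship_cache <- function(ped) {
  e <- new.env(parent = emptyenv())
  e$par <- ped_parents(ped)
  e$F <- inbreeding_coefficients(ped)$F
  e$memo <- new.env(parent = emptyenv(), size = 4L * nrow(ped))
  e
}

kin_pair <- function(cache, a, b) {
  if (a == 0L || b == 0L) return(0)
  if (a == b) return((1 + cache$F[[a]]) / 2)
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  key <- paste0(a, ":", b)
  hit <- cache$memo[[key]]
  if (!is.null(hit)) return(hit)
  # recurse on the later animal b: f(a,b) = (f(a, sire_b) + f(a, dam_b)) / 2
  s <- cache$par$sire[b]; d <- cache$par$dam[b]
  val <- (kin_pair(cache, a, s) + kin_pair(cache, a, d)) / 2
  assign(key, val, envir = cache$memo)
  val
}

#' Dense numerator relationship matrix (tabular method)
#'
#' Builds Wright's numerator relationship matrix A by the tabular method:
#' `A[i, j] = (A[s_i, j] + A[d_i, j]) / 2` for j preceding i and
#' `A[i, i] = 1 + A[s_i, d_i] / 2`. Quadratic in memory, so it is intended
#' for moderate pedigrees (a few thousand animals) and serves as the
#' independent cross-check for the recursive kinship and Meuwissen-Luo
#' routines (`F = diag(A) - 1`).
#'
#' @param ped a `pedigree`.
#' @return dense numeric matrix with animal ids as dimnames.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  par <- ped_parents(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- par$sire[i]; d <- par$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[s, j]
      if (d > 0L) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + (if (s > 0L && d > 0L) 0.5 * A[s, d] else 0)
  }
  A
}

#' Mean coancestry within or between groups
#'
#' Within-group mean kinship averages over unordered distinct pairs
#' (self-pairs excluded by default, matching the between-group convention);
#' between-group mean averages over all cross pairs and requires disjoint
#' groups. The default engine is the memoized pairwise recursion; the dense
#' tabular method is available for moderate pedigrees and used as an oracle
#' in the package tests.
#'
#' @param ped a `pedigree`.
#' @param groupA,groupB subset selectors; omit `groupB` (or pass `NULL`) for
#'   a within-group mean.
#' @param include_self if `TRUE`, within-group means also average the
#'   self-kinships `(1 + F)/2` (an alternative "total" convention).
#' @param method `"recursive"` or `"tabular"`.
#' @param cache optional kinship cache (see [kinship()]) reused across calls.
#' @return list with `mean_kinship` and `mean_relationship` (= 2 x kinship).
#' @export
mean_coancestry <- function(ped, groupA, groupB = NULL,
                            include_self = FALSE,
                            method = c("recursive", "tabular"),
                            cache = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  method <- match.arg(method)
  ia <- resolve_subset(ped, groupA)
  if (!length(ia)) stop("groupA is empty")
  between <- !is.null(groupB)
  if (between) {
    ib <- resolve_subset(ped, groupB)
    if (!length(ib)) stop("groupB is empty")
    ov <- intersect(ia, ib)
    if (length(ov)) stop("groups overlap: ", paste(ped$id[ov], collapse = ", "))
  }

  if (method == "tabular") {
    A <- relationship_matrix(ped)
    if (between) {
      mk <- mean(A[ia, ib, drop = FALSE]) / 2
    } else {
      if (length(ia) == 1L && !include_self) return(undefined_mean())
      M <- A[ia, ia, drop = FALSE] / 2
      mk <- if (include_self) mean(M) else {
        (sum(M) - sum(diag(M))) / (length(ia) * (length(ia) - 1L))
      }
    }
  } else {
    if (is.null(cache)) cache <- new_kinship_cache(ped)
    if (between) {
      tot <- 0
      for (i in ia) for (j in ib) tot <- tot + kin_pair(cache, i, j)
      mk <- tot / (length(ia) * length(ib))
    } else {
      if (length(ia) == 1L && !include_self) return(undefined_mean())
      tot <- 0
      if (length(ia) > 1L) {
        for (u in seq_along(ia)[-length(ia)]) {
          for (v in (u + 1L):length(ia)) tot <- tot + kin_pair(cache, ia[u], ia[v])
        }
      }
      n_pairs <- length(ia) * (length(ia) - 1L) / 2
      if (include_self) {
        # matrix-mean convention: every unordered pair twice, self once
        mk <- (2 * tot + sum((1 + cache$F[ia]) / 2)) / length(ia)^2
      } else {
        mk <- tot / n_pairs
      }
    }
  }
  list(mean_kinship = mk, mean_relationship = 2 * mk)
}

undefined_mean <- function() list(mean_kinship = NA_real_,
                                  mean_relationship = NA_real_)
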