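#' Split animals into report groups
#'
#' @param ped a `pedigree`.
#' @param group_by `"birth_year"`, `"studbook"`, `"sex"` or `"none"`.
#' @param reference_only restrict to the reference population first.
#' @return named list of integer row-index vectors; empty groups dropped
#'   with a message.
#' @keywords internal
split_groups <- function(ped, group_by = c("birth_year", "studbook", "sex", "none"),
                         reference_only = TRUE) {
  group_by <- match.arg(group_by)
  idx <- if (reference_only) which(ped$in_reference) else seq_len(nrow(ped))
  if (!length(idx)) stop("no animals selected (is in_reference set?)")
  if (group_by == "none") return(list(all = idx))
  key <- as.character(ped[[group_by]][idx])
  known <- !is.na(key)
  if (any(!known)) {
    message(sum(!known), " animal(s) without ", group_by, " dropped from grouping")
  }
  g <- split(idx[known], key[known])
  g[order(names(g))]
}

#' Group-level homozygosity summary
#'
#' The Table-5/6-style report: per group, the number of animals, mean
#' inbreeding coefficient (%), percentage of inbred animals (F > 0), mean
#' pairwise coancestry within the group (%), mean individual increase in
#' inbreeding (%) and the realized effective population size
#' `Ne = 1/(2 mean dF)`.
#'
#' @param ped a `pedigree`.
#' @param group_by grouping key (see [split_groups()]).
#' @param reference_only summarize the reference population only.
#' @param include_self include self-kinships in the within-group coancestry
#'   mean (alternative convention).
#' @param coancestry_method `"recursive"` or `"tabular"`.
#' @return data frame of class `relatedness_summary`: one row per group plus
#'   a pooled `total` row, with columns `group`, `n`, `F_pct`,
#'   `pct_inbred`, `mean_coancestry_pct`, `delta_F_pct`, `Ne`.
#' @export
relatedness_summary <- function(ped, group_by = "birth_year",
                                reference_only = TRUE,
                                include_self = FALSE,
                                coancestry_method = "recursive") {
  stopifnot(inherits(ped, "pedigree"))
  groups <- split_groups(ped, group_by, reference_only)
  Fv <- inbreeding_coefficients(ped)$F
  ge <- equivalent_generations(ped, individuals = "all")$g_e
  dF <- delta_F(Fv, ge)
  cache <- new_kinship_cache(ped)

  one <- function(label, idx) {
    mdF <- mean(dF[idx], na.rm = TRUE)
    data.frame(
      group = label, n = length(idx),
      F_pct = 100 * mean(Fv[idx]),
      pct_inbred = 100 * mean(Fv[idx] > 0),
      mean_coancestry_pct = 100 * mean_coancestry(
        ped, idx, include_self = include_self,
        method = coancestry_method, cache = cache)$mean_kinship,
      delta_F_pct = 100 * mdF,
      Ne = effective_population_size(dF[idx]),
      stringsAsFactors = FALSE
    )
  }
  rows <- Map(one, names(groups), groups)
  out <- do.call(rbind, rows)
  if (length(groups) > 1L) {
    all_idx <- sort(unique(unlist(groups)))
    out <- rbind(out, one("total", all_idx))
  }
  rownames(out) <- NULL
  class(out) <- c("relatedness_summary", "data.frame")
  out
}

#' Group-level gene-origin diversity summary
#'
#' Per group (used as its own reference population): founder contributions,
#' effective number of founders, gene-drop founder genome equivalent,
#' effective number of non-founders and the GD/GD* diversity measures.
#'
#' @param ped a `pedigree`.
#' @param group_by,reference_only as in [relatedness_summary()].
#' @param replicates gene-drop replicates per group.
#' @param seed master seed; each group gets a deterministic sub-seed.
#' @return data frame: one row per group plus `total`, columns `group`, `n`,
#'   `f_e`, `f_ge`, `N_enf`, `GD`, `GD_star`, `loss_total_pct`,
#'   `loss_founder_pct`, `loss_drift_pct`.
#' @export
diversity_summary <- function(ped, group_by = "birth_year",
                              reference_only = TRUE,
                              replicates = 10000L, seed = 1L) {
  stopifnot(inherits(ped, "pedigree"))
  groups <- split_groups(ped, group_by, reference_only)
  if (length(groups) > 1L) groups$total <- sort(unique(unlist(groups)))

  one <- function(label, idx, sub_seed) {
    pc <- founder_contributions(ped, reference = idx)
    fe <- effective_founders(pc)
    gd <- gene_drop(ped, reference = idx, replicates = replicates,
                    seed = sub_seed)
    fge <- founder_genome_equivalent(pc, gd)
    dv <- genetic_diversity(fe, fge)
    data.frame(group = label, n = length(idx), f_e = fe, f_ge = fge,
               N_enf = dv$N_enf, GD = dv$GD, GD_star = dv$GD_star,
               loss_total_pct = 100 * dv$loss_total,
               loss_founder_pct = 100 * dv$loss_founder,
               loss_drift_pct = 100 * dv$loss_drift,
               stringsAsFactors = FALSE)
  }
  rows <- Map(one, names(groups), groups,
              stage_seed(seed, seq_along(groups)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicates") <- replicates
  attr(out, "seed") <- seed
  class(out) <- c("diversity_summary", "data.frame")
  out
}

# deterministic per-stage sub-seeds below 2^31
stage_seed <- function(master, k) {
  (as.numeric(master) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

#' Per-year diversity-loss series
#'
#' Aligns the total loss `1 - GD` (founder inequality plus drift and
#' bottlenecks) and the founder-only loss `1 - GD*` on the percent scale,
#' one row per group of a [diversity_summary()]. `1 - GD >= 1 - GD*` always.
#'
#' @param diversity a `diversity_summary` (the `total` row is dropped).
#' @return data frame with `group`, `loss_total_pct`, `loss_founder_pct`,
#'   `loss_drift_pct`.
#' @export
diversity_loss_series <- function(diversity) {
  stopifnot(inherits(diversity, "diversity_summary") || is.data.frame(diversity))
  d <- diversity[diversity$group != "total",
                 c("group", "loss_total_pct", "loss_founder_pct", "loss_drift_pct")]
  rownames(d) <- NULL
  d
}

#' Within/between group mean numerator relationships
#'
#' The Table-7-style matrix: mean numerator relationship (%) within each
#' group on the diagonal and between groups off the diagonal. A singleton
#' group has no distinct within-group pair and reports `NA` on its diagonal.
#'
#' @param ped a `pedigree`.
#' @param group_by grouping key (default `"studbook"`).
#' @param reference_only restrict to reference animals.
#' @param method `"recursive"` or `"tabular"` (see [mean_coancestry()]).
#' @return symmetric numeric matrix (percent scale) with group labels.
#' @export
between_group_table <- function(ped, group_by = "studbook",
                                reference_only = TRUE,
                                method = "recursive") {
  groups <- split_groups(ped, group_by, reference_only)
  if (length(groups) < 2L) stop("need at least two groups")
  k <- length(groups)
  M <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  cache <- if (method == "recursive") new_kinship_cache(ped) else NULL
  A <- if (method == "tabular") relationship_matrix(ped) else NULL
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (method == "tabular") {
        gi <- groups[[i]]; gj <- groups[[j]]
        val <- if (i == j) {
          if (length(gi) < 2L) NA_real_ else {
            S <- A[gi, gi, drop = FALSE]
            (sum(S) - sum(diag(S))) / (length(gi) * (length(gi) - 1L))
          }
        } else mean(A[gi, gj, drop = FALSE])
      } else {
        mc <- if (i == j) {
          mean_coancestry(ped, groups[[i]], include_self = FALSE,
                          method = "recursive", cache = cache)
        } else {
          mean_coancestry(ped, groups[[i]], groups[[j]],
                          method = "recursive", cache = cache)
        }
        val <- mc$mean_relationship
      }
      M[i, j] <- M[j, i] <- 100 * val
    }
  }
  M
}

#' Run the full pedigree analysis
#'
#' Orchestrates the pipeline - read/validate, structure counts, equivalent
#' generations, completeness, generation intervals, grouped homozygosity and
#' gene-origin diversity, between-group relationships and the founder
#' decomposition of mean inbreeding - into one bundle. All stochastic stages
#' are seeded deterministically from the single `seed`, so a bundle is
#' reproducible bit for bit.
#'
#' @param ped a `pedigree`, or a file path passed to [read_pedigree()].
#' @param group_by grouping for the per-group tables.
#' @param depth completeness depth in generations.
#' @param interval_mode see [generation_intervals()].
#' @param replicates gene-drop replicates.
#' @param decomposition_method see [inbreeding_decomposition()].
#' @param seed master seed for every stochastic stage.
#' @param reference_only restrict grouped tables to the reference population.
#' @return list of class `analysis_bundle`.
#' @export
run_analysis <- function(ped, group_by = "birth_year", depth = 5L,
                         interval_mode = "reproducing_offspring",
                         replicates = 10000L,
                         decomposition_method = "exact_recursive",
                         seed = 1L, reference_only = TRUE) {
  if (is.character(ped)) ped <- read_pedigree(ped)
  stopifnot(inherits(ped, "pedigree"))
  issues <- validate_pedigree(ped)
  if (any(issues$severity == "error")) {
    stop("pedigree validation failed:\n  ",
         paste(issues$message[issues$severity == "error"], collapse = "\n  "))
  }
  ref_sel <- if (any(ped$in_reference) && reference_only) "reference" else "all"
  intervals <- tryCatch(generation_intervals(ped, mode = interval_mode),
                        error = function(e) NULL)
  grouping_possible <- group_by == "none" ||
    length(unique(stats::na.omit(ped[[group_by]]))) >= 1L
  decomposition <- tryCatch(
    inbreeding_decomposition(ped, reference = ref_sel,
                             method = decomposition_method,
                             replicates = replicates,
                             seed = stage_seed(seed, 1L)),
    error = function(e) NULL)
  relmat <- tryCatch(
    between_group_table(ped, group_by = if (group_by == "birth_year") "studbook" else group_by,
                        reference_only = reference_only),
    error = function(e) NULL)

  bundle <- list(
    structure = count_structure(ped, reference = "all"),
    equivalent_generations = equivalent_generations(ped, individuals = ref_sel),
    completeness = pedigree_completeness(ped, individuals = ref_sel, depth = depth),
    generation_intervals = intervals,
    relatedness = relatedness_summary(ped, group_by = group_by,
                                      reference_only = reference_only),
    diversity = diversity_summary(ped, group_by = group_by,
                                  reference_only = reference_only,
                                  replicates = replicates,
                                  seed = stage_seed(seed, 2L)),
    group_relationships = relmat,
    decomposition = decomposition,
    validation = issues,
    metadata = list(seed = seed, replicates = replicates, depth = depth,
                    group_by = group_by, interval_mode = interval_mode,
                    decomposition_method = decomposition_method,
                    reference_only = reference_only,
                    n_animals = nrow(ped),
                    package_version = as.character(utils::packageVersion("studbook")),
                    timestamp = format(Sys.time(), tz = "UTC"))
  )
  class(bundle) <- "analysis_bundle"
  bundle
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("== Pedigree analysis bundle ==\n")
  print(x$structure)
  if (!is.null(x$generation_intervals)) print(x$generation_intervals)
  cat("\nHomozygosity by group:\n")
  print(format_group_summary(x$relatedness), row.names = FALSE)
  cat("\nGene-origin diversity by group:\n")
  print(format_group_summary(x$diversity), row.names = FALSE)
  invisible(x)
}

#' Display-round a group summary the way studbook reports print it
#'
#' Percent columns to 3 decimals; `Ne`, `f_e`, `f_ge`, `N_enf` to the
#' nearest integer. Purely a display transformation of the full-precision
#' table: nothing is recomputed.
#'
#' @param df a `relatedness_summary` or `diversity_summary`.
#' @return data frame of formatted values.
#' @export
format_group_summary <- function(df) {
  out <- as.data.frame(df)
  for (nm in names(out)) {
    if (nm %in% c("Ne", "f_e", "f_ge", "N_enf")) {
      out[[nm]] <- ifelse(is.finite(out[[nm]]), round(out[[nm]]), NA)
    } else if (grepl("pct$|_pct|^F_pct", nm)) {
      out[[nm]] <- round(out[[nm]], 3)
    } else if (is.numeric(out[[nm]])) {
      out[[nm]] <- round(out[[nm]], 5)
    }
  }
  out
}
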