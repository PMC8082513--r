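#' Build a validated, topologically ordered pedigree
#'
#' A `pedigree` is a data frame with one row per animal and columns `id`,
#' `sire`, `dam` (character; `NA` = unknown parent), `sex` (`"M"`, `"F"` or
#' `"U"`), `birth_year` (integer or `NA`), `studbook` (character or `NA`) and
#' `in_reference` (logical). Rows are stored parent-first: every sire and dam
#' precedes all of its offspring, which is what the recursive estimators
#' (inbreeding, kinship, gene dropping) require.
#'
#' Parents that are referenced in the `sire`/`dam` columns but have no row of
#' their own are materialized as founder records with missing metadata, as
#' studbook extracts routinely omit founder rows. Identifier comparison is
#' exact string matching: no case folding, no whitespace trimming beyond the
#' file reader's.
#'
#' @param df data frame with at least `id`, `sire` and `dam` columns. Unknown
#'   parents may be coded `NA`, `""`, `"0"` or `"NA"`.
#' @return An object of class `pedigree`.
#' @examples
#' ped <- pedigree(data.frame(id = "C", sire = "A", dam = "B"))
#' nrow(ped)  # 3: A and B are auto-created founders
#' @export
pedigree <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("id", "sire", "dam")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("pedigree table lacks required column(s): ", paste(miss, collapse = ", "))
  }
  id   <- as.character(df$id)
  sire <- normalize_parent(df$sire)
  dam  <- normalize_parent(df$dam)

  if (anyNA(id) || any(!nzchar(id))) {
    stop("empty or missing animal identifier in row(s) ",
         paste(which(is.na(id) | !nzchar(id)), collapse = ", "))
  }
  if (anyDuplicated(id)) {
    stop("duplicate animal identifier(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(sire == id, na.rm = TRUE) || any(dam == id, na.rm = TRUE)) {
    bad <- id[(sire == id & !is.na(sire)) | (dam == id & !is.na(dam))]
    stop("animal recorded as its own parent: ", paste(bad, collapse = ", "))
  }

  sex <- if ("sex" %in% names(df)) normalize_sex(df$sex) else rep("U", length(id))
  birth_year <- if ("birth_year" %in% names(df)) {
    suppressWarnings(as.integer(df$birth_year))
  } else rep(NA_integer_, length(id))
  studbook <- if ("studbook" %in% names(df)) {
    sb <- as.character(df$studbook)
    sb[!is.na(sb) & !nzchar(sb)] <- NA_character_
    sb
  } else rep(NA_character_, length(id))
  in_reference <- if ("in_reference" %in% names(df)) {
    as_flag(df$in_reference)
  } else rep(FALSE, length(id))

  out <- data.frame(
    id = id, sire = sire, dam = dam, sex = sex, birth_year = birth_year,
    studbook = studbook, in_reference = in_reference,
    stringsAsFactors = FALSE
  )

  # materialize parents that never appear as rows
  referenced <- unique(c(sire[!is.na(sire)], dam[!is.na(dam)]))
  phantom_rows <- setdiff(referenced, id)
  if (length(phantom_rows)) {
    as_sire <- phantom_rows %in% sire
    as_dam  <- phantom_rows %in% dam
    aug <- data.frame(
      id = phantom_rows, sire = NA_character_, dam = NA_character_,
      sex = ifelse(as_sire & !as_dam, "M", ifelse(as_dam & !as_sire, "F", "U")),
      birth_year = NA_integer_, studbook = NA_character_,
      in_reference = FALSE, stringsAsFactors = FALSE
    )
    out <- rbind(aug, out)
    message(length(phantom_rows),
            " parent(s) referenced without a record; auto-created as founders")
  }
  attr(out, "n_autocreated") <- length(phantom_rows)
  out <- topological_order(as_pedigree_raw(out))
  out
}

as_pedigree_raw <- function(df) {
  class(df) <- c("pedigree", "data.frame")
  df
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("", "0", "NA")] <- NA_character_
  x
}

normalize_sex <- function(x) {
  x <- toupper(as.character(x))
  x[x %in% c("M", "MALE", "1")] <- "M"
  x[x %in% c("F", "FEMALE", "2")] <- "F"
  x[is.na(x) | !(x %in% c("M", "F"))] <- "U"
  x
}

as_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- as.character(x)
  !is.na(x) & x %in% c("1", "TRUE", "true", "T", "yes")
}

#' Parent row indices of a pedigree
#'
#' @param ped a `pedigree`.
#' @return list with integer vectors `sire` and `dam`; 0 marks an unknown
#'   parent. Indices refer to rows of `ped` (topological order).
#' @keywords internal
ped_parents <- function(ped) {
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  s[is.na(s)] <- 0L
  d[is.na(d)] <- 0L
  list(sire = s, dam = d)
}

is_founder <- function(ped) is.na(ped$sire) & is.na(ped$dam)

#' Read a pedigree file
#'
#' Supports two dialects: a CSV with header columns
#' `id,sire,dam[,sex,birth_year,studbook,in_reference]` (extra columns are
#' ignored), and the classic whitespace-delimited three-column
#' `id sire dam` pedigree-software format where `0` codes an unknown parent.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"three_column"`.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path, dialect = c("csv", "three_column")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
    if (!all(c("id", "sire", "dam") %in% names(df))) {
      stop("CSV pedigree needs header columns id, sire, dam; got: ",
           paste(names(df), collapse = ", "))
    }
  } else {
    df <- utils::read.table(path, header = FALSE, colClasses = "character")
    if (ncol(df) < 3) {
      stop("three-column pedigree must have >= 3 whitespace-delimited fields")
    }
    df <- df[, 1:3]
    names(df) <- c("id", "sire", "dam")
  }
  pedigree(df)
}

#' Write a pedigree to CSV
#'
#' Inverse of [read_pedigree()] for the CSV dialect; unknown parents are
#' written as empty fields. A read -> write -> read round trip reproduces the
#' pedigree exactly.
#'
#' @param ped a `pedigree`.
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- as.data.frame(ped)
  out$in_reference <- as.integer(out$in_reference)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Stable topological (parent-first) ordering
#'
#' Reorders rows so that every known parent precedes all of its offspring.
#' The order is stable: among animals not constrained relative to each other,
#' the original row order is preserved, so input that is already parent-first
#' comes back unchanged.
#'
#' @param ped a `pedigree` (or raw pedigree data frame).
#' @return The reordered `pedigree`.
#' @export
topological_order <- function(ped) {
  n <- nrow(ped)
  if (n == 0L) return(ped)
  par <- ped_parents(ped)
  edges_from <- c(par$sire, par$dam)
  edges_to <- rep(seq_len(n), 2L)
  keep <- edges_from > 0L
  edges_from <- edges_from[keep]
  edges_to <- edges_to[keep]

  indeg <- tabulate(edges_to, nbins = n)
  # children adjacency: for each parent, the offspring rows
  ord_e <- order(edges_from)
  child_of <- split(edges_to[ord_e], edges_from[ord_e])

  avail <- sort(which(indeg == 0L))
  out <- integer(n)
  k <- 0L
  while (length(avail)) {
    i <- avail[1L]
    avail <- avail[-1L]
    k <- k + 1L
    out[k] <- i
    kids <- child_of[[as.character(i)]]
    if (!is.null(kids)) {
      for (ch in kids) {
        indeg[ch] <- indeg[ch] - 1L
        if (indeg[ch] == 0L) {
          pos <- findInterval(ch, avail)
          avail <- append(avail, ch, after = pos)
        }
      }
    }
  }
  if (k < n) {
    left <- setdiff(seq_len(n), out[seq_len(k)])
    cyc <- trace_cycle(left, par)
    stop("pedigree contains a cycle involving: ",
         paste(ped$id[cyc], collapse = " -> "))
  }
  res <- ped[out, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_autocreated") <- attr(ped, "n_autocreated")
  class(res) <- c("pedigree", "data.frame")
  res
}

# walk parent pointers within the unplaced set until a node repeats
trace_cycle <- function(left, par) {
  in_left <- logical(max(left))
  in_left[left] <- TRUE
  cur <- left[1L]
  seen <- integer(0)
  while (!(cur %in% seen)) {
    seen <- c(seen, cur)
    nxt <- c(par$sire[cur], par$dam[cur])
    nxt <- nxt[nxt > 0L & nxt <= length(in_left)]
    nxt <- nxt[in_left[nxt]]
    if (!length(nxt)) return(seen)
    cur <- nxt[1L]
  }
  seen[which(seen == cur)[1L]:length(seen)]
}

#' Validate a pedigree and report issues
#'
#' Report-only: nothing is fixed or rejected here. Issues are returned with a
#' severity so that callers can decide what to tolerate. Chronology problems
#' (offspring born before or with a parent) are warnings, not errors, because
#' historical studbooks contain year typos and no downstream estimator uses
#' birth years except for grouping and generation intervals.
#'
#' @param ped a `pedigree`.
#' @return data frame with columns `severity` (`"error"`, `"warning"`,
#'   `"info"`), `code` and `message`; zero rows when nothing is wrong.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  issues <- list()
  add <- function(severity, code, msg) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, code = code, message = msg,
      stringsAsFactors = FALSE
    )
  }

  ord_ok <- tryCatch({ topological_order(ped); TRUE },
                     error = function(e) { add("error", "cycle", conditionMessage(e)); FALSE })

  sires <- unique(ped$sire[!is.na(ped$sire)])
  dams  <- unique(ped$dam[!is.na(ped$dam)])
  both  <- intersect(sires, dams)
  for (b in both) {
    add("error", "role_conflict",
        paste0("'", b, "' appears both as a sire and as a dam"))
  }
  sx <- ped$sex[match(sires, ped$id)]
  for (b in sires[!is.na(sx) & sx == "F"]) {
    add("error", "sex_conflict", paste0("female '", b, "' used as a sire"))
  }
  dx <- ped$sex[match(dams, ped$id)]
  for (b in dams[!is.na(dx) & dx == "M"]) {
    add("error", "sex_conflict", paste0("male '", b, "' used as a dam"))
  }

  par <- ped_parents(ped)
  by <- ped$birth_year
  for (side in c("sire", "dam")) {
    p <- par[[side]]
    has <- p > 0L & !is.na(by) & !is.na(by[pmax(p, 1L)])
    bad <- which(has & by <= by[pmax(p, 1L)])
    for (i in bad) {
      add("warning", "chronology",
          paste0("'", ped$id[i], "' (", by[i], ") born in or before the birth year of ",
                 side, " '", ped$id[p[i]], "' (", by[p[i]], ")"))
    }
  }

  n_missing_year <- sum(is.na(by))
  if (n_missing_year) {
    add("info", "missing_birth_year",
        paste0(n_missing_year, " animal(s) without birth year"))
  }
  n_missing_sex <- sum(ped$sex == "U")
  if (n_missing_sex) {
    add("info", "missing_sex", paste0(n_missing_sex, " animal(s) with unknown sex"))
  }
  if (!length(issues)) {
    return(data.frame(severity = character(0), code = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' @export
print.pedigree <- function(x, ...) {
  n <- nrow(x)
  nf <- sum(is_founder(x))
  cat(sprintf("<pedigree> %d animals (%d founders, %d in reference)\n",
              n, nf, sum(x$in_reference)))
  NextMethod()
}

#' Write an analysis report to disk
#'
#' Writes any of the package's report objects (data frames or lists of
#' data-frame components such as the bundle from [run_analysis()]) as CSV or
#' JSON. Values are written at full precision; rounding is applied only by
#' the display formatters.
#'
#' @param report a data frame, or a named list of data frames / scalars.
#' @param path output file path.
#' @param format `"csv"` or `"json"`. CSV requires a data frame (or a list of
#'   them, written as `<path stem>-<name>.csv`).
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    return(invisible(path))
  }
  if (is.data.frame(report)) {
    utils::write.csv(report, path, row.names = FALSE, na = "")
  } else if (is.list(report)) {
    stem <- sub("\\.csv$", "", path)
    for (nm in names(report)) {
      if (is.data.frame(report[[nm]])) {
        utils::write.csv(report[[nm]], paste0(stem, "-", nm, ".csv"),
                         row.names = FALSE, na = "")
      }
    }
  } else {
    stop("cannot write a ", class(report)[1], " as CSV")
  }
  invisible(path)
}
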