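# Arm-level data model for randomized concurrent controlled trial (RCCT) counts.
#
# The universal input is one row per trial arm: a study identifier, the source
# review, the intervention category, the arm role (control / intervention), the
# pneumonia event count and the group size.  Multi-arm trials are encoded as
# one pseudo-study per comparison, with the repeated control arm carrying
# `shared_control_of` = the study_id holding the physical control group.

ARM_CATEGORIES <- c("non_antimicrobial", "antimicrobial", "antimicrobial_duplex")
ARM_ROLES <- c("control", "intervention")

ARM_COLUMNS <- c(
  "study_id", "review_id", "category", "subcategory",
  "arm_role", "events", "total", "shared_control_of"
)

#' Construct and validate an arm-level study table
#'
#' An `arm_table` is a plain `data.frame` (one row per trial arm) carrying the
#' event count and group size of every control and intervention group in a
#' collection of randomized concurrent controlled trials, together with
#' category metadata. All analysis functions in the package consume this
#' layout.
#'
#' @param df A data.frame with columns `study_id`, `review_id`, `category`
#'   (one of `"non_antimicrobial"`, `"antimicrobial"`,
#'   `"antimicrobial_duplex"`), `subcategory`, `arm_role` (`"control"` or
#'   `"intervention"`), `events` (non-negative integer), `total` (positive
#'   integer), and optionally `shared_control_of` (study_id whose physical
#'   control group this control arm duplicates; `NA` otherwise).
#' @param provenance Free-text note recording where the rows came from.
#'
#' @return A validated data.frame of class `arm_table`, row order preserved.
#' @export
arm_table <- function(df, provenance = "unspecified") {
  stopifnot(is.data.frame(df))
  if (!"shared_control_of" %in% names(df)) df$shared_control_of <- NA_character_
  missing_cols <- setdiff(ARM_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("arm_table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, ARM_COLUMNS]
  for (col in c("study_id", "review_id", "category", "subcategory", "arm_role",
                "shared_control_of")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$shared_control_of[!is.na(df$shared_control_of) &
                         !nzchar(df$shared_control_of)] <- NA_character_
  df$events <- as.integer(df$events)
  df$total <- as.integer(df$total)
  rownames(df) <- NULL

  if (nrow(df) == 0L) {
    warning("arm_table has zero records")
  } else {
    validate_arm_table(df)
  }
  structure(df, class = c("arm_table", "data.frame"), provenance = provenance)
}

validate_arm_table <- function(df) {
  bad <- !df$category %in% ARM_CATEGORIES
  if (any(bad)) {
    stop("unknown category '", df$category[bad][1], "' (study ",
         df$study_id[bad][1], ")")
  }
  bad <- !df$arm_role %in% ARM_ROLES
  if (any(bad)) {
    stop("unknown arm_role '", df$arm_role[bad][1], "' (study ",
         df$study_id[bad][1], ")")
  }
  if (anyNA(df$events) || anyNA(df$total)) {
    stop("events/total contain missing or non-numeric values")
  }
  bad <- df$total < 1L
  if (any(bad)) stop("total must be >= 1 (study ", df$study_id[bad][1], ")")
  bad <- df$events < 0L | df$events > df$total
  if (any(bad)) {
    stop("events outside [0, total] for study ", df$study_id[bad][1])
  }
  key <- paste(df$study_id, df$arm_role, df$subcategory, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df$study_id[duplicated(key)][1]
    stop("duplicate study_id/arm_role/subcategory combination (study ", dup, ")")
  }
  # a study may lack its own control arm only when its rows point at the
  # study holding the shared physical control (post include_once dedup)
  linked <- split(!is.na(df$shared_control_of), df$study_id)
  roles <- split(df$arm_role, df$study_id)
  incomplete <- names(roles)[!vapply(
    names(roles),
    function(s) all(ARM_ROLES %in% roles[[s]]) || all(linked[[s]]),
    logical(1)
  )]
  if (length(incomplete)) {
    stop("study ", incomplete[1], " lacks a control or an intervention arm")
  }
  dangling <- setdiff(
    df$shared_control_of[!is.na(df$shared_control_of)], df$study_id
  )
  if (length(dangling)) {
    stop("shared_control_of references unknown study ", dangling[1])
  }
  invisible(df)
}

#' Read an arm-level study table from CSV
#'
#' @param path Path to a CSV file with a header row naming the `arm_table`
#'   columns and one row per arm; `shared_control_of` may be blank.
#'
#' @return An [arm_table] with rows in file order. A header-only file yields a
#'   zero-row table with a warning.
#' @export
read_arm_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  missing_cols <- setdiff(setdiff(ARM_COLUMNS, "shared_control_of"), names(df))
  if (length(missing_cols)) {
    stop("malformed header in ", path, ": missing ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) > 0) {
    counts <- suppressWarnings(cbind(as.numeric(df$events), as.numeric(df$total)))
    bad <- which(!stats::complete.cases(counts))
    if (length(bad)) {
      stop("malformed row ", bad[1] + 1L, " in ", path,
           ": events/total not numeric")
    }
  }
  arm_table(df, provenance = path)
}

#' Write an arm-level study table to CSV
#'
#' Round-trips through [read_arm_table()].
#'
#' @param table An [arm_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_arm_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Arrange paired counts in the diagnostic-test 2x2 layout
#'
#' Each study's counts are rewritten as a 2x2 table in which the intervention
#' arm plays the "diseased" group and the control arm the "non-diseased" group
#' of a diagnostic test assessment: `tp` = intervention events, `fn` =
#' intervention non-events, `fp` = control events, `tn` = control non-events.
#' Under this mapping the intervention-group incidence plays "sensitivity" and
#' the control-group incidence plays 1 - "specificity".
#'
#' @param table An [arm_table] with exactly one control and one intervention
#'   arm per `study_id` (apply [dedupe_control_arms()] first for multi-arm
#'   trials).
#'
#' @return A data.frame with columns `study_id`, `tp`, `fn`, `fp`, `tn`,
#'   `category`, in input study order.
#' @export
to_dta_layout <- function(table) {
  ids <- unique(table$study_id)
  out <- lapply(ids, function(id) {
    rows <- table[table$study_id == id, ]
    ctrl <- rows[rows$arm_role == "control", ]
    int <- rows[rows$arm_role == "intervention", ]
    if (nrow(ctrl) != 1L || nrow(int) != 1L) {
      stop("study ", id, " does not have exactly one control and one ",
           "intervention arm; dedupe/split multi-arm studies first")
    }
    data.frame(
      study_id = id,
      tp = int$events, fn = int$total - int$events,
      fp = ctrl$events, tn = ctrl$total - ctrl$events,
      category = ctrl$category,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Resolve duplicated control groups of multi-arm trials
#'
#' A physical control group shared by several comparisons appears once with
#' `shared_control_of = NA` and once more per additional comparison with
#' `shared_control_of` pointing back at the holder.
#'
#' * `mode = "include_once"` keeps each physical control group exactly once
#'   (drop the duplicate copies) — appropriate for arm-based pooling, where a
#'   patient must not be counted twice.
#' * `mode = "split"` divides the control events and totals as evenly as
#'   integers allow across the comparisons sharing them — appropriate for
#'   contrast-based pairing. Totals and events are conserved exactly; when the
#'   split is uneven the larger share goes to the earliest comparison in input
#'   order.
#'
#' @param table An [arm_table].
#' @param mode `"include_once"` or `"split"`.
#' @return An [arm_table].
#' @export
dedupe_control_arms <- function(table, mode = c("include_once", "split")) {
  mode <- match.arg(mode)
  df <- as.data.frame(table)
  is_dup <- df$arm_role == "control" & !is.na(df$shared_control_of)

  if (mode == "include_once") {
    # drop the duplicate control rows; the orphaned comparisons keep a
    # shared_control_of marker naming the study holding their physical control
    orphan <- df$study_id %in% df$study_id[is_dup]
    holder <- df$shared_control_of[is_dup][match(df$study_id[orphan],
                                                 df$study_id[is_dup])]
    df$shared_control_of[orphan] <- holder
    out <- df[!is_dup, ]
    return(arm_table(out, provenance = attr(table, "provenance") %||% "dedupe"))
  }

  # split: for every physical control group, divide events/totals across the
  # holder and its duplicates, earliest comparison first.
  holders <- unique(df$shared_control_of[is_dup])
  for (holder in holders) {
    idx <- which(df$arm_role == "control" &
                   (df$study_id == holder |
                      (!is.na(df$shared_control_of) &
                         df$shared_control_of == holder)))
    # input order: the holder's own row first, then duplicates as encountered
    idx <- idx[order(df$study_id[idx] != holder, idx)]
    m <- length(idx)
    src <- df[idx[1], ]
    df$events[idx] <- int_split(src$events, m)
    df$total[idx] <- int_split(src$total, m)
  }
  df$shared_control_of <- NA_character_
  arm_table(df, provenance = attr(table, "provenance") %||% "dedupe")
}

# divide integer x into m integer shares, as even as possible, larger shares first
int_split <- function(x, m) {
  base <- x %/% m
  extra <- x %% m
  base + as.integer(seq_len(m) <= extra)
}

#' Subset studies by control-group incidence
#'
#' Retains whole studies whose control-arm incidence `events/total` lies
#' strictly above (or strictly below) a threshold. Studies sitting exactly at
#' the threshold are excluded from both strata; a message reports how many.
#'
#' @param table An [arm_table] (one control arm per study).
#' @param threshold Incidence threshold in (0, 1), e.g. `0.4`.
#' @param side `"above"` or `"below"`.
#' @return An [arm_table] containing the retained studies.
#' @export
filter_by_control_incidence <- function(table, threshold,
                                        side = c("above", "below")) {
  side <- match.arg(side)
  stopifnot(threshold > 0, threshold < 1)
  df <- as.data.frame(table)
  ctrl <- df[df$arm_role == "control" & is.na(df$shared_control_of), ]
  inc <- ctrl$events / ctrl$total
  at_boundary <- ctrl$study_id[inc == threshold]
  if (length(at_boundary)) {
    message(length(at_boundary), " study(ies) at control incidence exactly ",
            threshold, " excluded from both strata")
  }
  keep <- if (side == "above") ctrl$study_id[inc > threshold] else
    ctrl$study_id[inc < threshold]
  out <- df[df$study_id %in% keep, ]
  if (nrow(out) == 0L) {
    return(suppressWarnings(arm_table(out, provenance = "filter")))
  }
  arm_table(out, provenance = attr(table, "provenance") %||% "filter")
}

#' @export
print.arm_table <- function(x, ...) {
  cat("<arm_table> ", length(unique(x$study_id)), " studies, ",
      nrow(x), " arms (", sum(x$arm_role == "control"), " control / ",
      sum(x$arm_role == "intervention"), " intervention)\n", sep = "")
  cat("categories:",
      paste(sprintf("%s=%d", names(table(x$category)), table(x$category)),
            collapse = ", "), "\n")
  invisible(x)
}
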