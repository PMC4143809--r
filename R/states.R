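#' Assign a hypertension state from one examination record
#'
#' Classifies a single exam into one of three blood-pressure states:
#' state 1 (normotensive) when SBP < 120 mm Hg and DBP < 80 mm Hg;
#' state 2 (prehypertensive) when not in state 1 but SBP < 140 and DBP < 90;
#' state 3 (hypertensive) otherwise. Use of antihypertensive medication
#' forces state 3 regardless of the recorded pressures. Thresholds are
#' strict: an exam at exactly 120/80 or 140/90 falls in the higher state.
#'
#' @param sbp systolic blood pressure, mm Hg (positive).
#' @param dbp diastolic blood pressure, mm Hg (positive).
#' @param meds logical, antihypertensive medication use at this exam.
#' @return integer vector of states in \code{{1, 2, 3}}.
#' @examples
#' assign_state(118, 75, FALSE) # 1
#' assign_state(119, 85, FALSE) # 2
#' assign_state(100, 60, TRUE)  # 3 (medication override)
#' @export
assign_state <- function(sbp, dbp, meds) {
  n <- max(length(sbp), length(dbp), length(meds))
  sbp <- rep_len(as.numeric(sbp), n)
  dbp <- rep_len(as.numeric(dbp), n)
  meds <- rep_len(as.logical(meds), n)
  if (anyNA(sbp) || anyNA(dbp) || anyNA(meds))
    stop("assign_state() requires complete sbp, dbp and meds; ",
         "filter incomplete exams first (see build_state_sequences)")
  if (any(sbp <= 0) || any(dbp <= 0))
    stop("blood pressures must be positive")
  state <- ifelse(sbp < 120 & dbp < 80, 1L,
                  ifelse(sbp < 140 & dbp < 90, 2L, 3L))
  state[meds] <- 3L
  as.integer(state)
}

.clinical_vars <- c("sbp", "dbp", "meds", "sex", "smoke", "age")

#' Build per-subject hypertension state sequences
#'
#' Takes a long-format examination table (one row per subject and exam),
#' drops exams with any missing clinical variable (sbp, dbp, meds, sex,
#' smoke, age), drops subjects left with no exams, orders the remainder by
#' exam index and assigns states with [assign_state()].
#'
#' @param records data.frame with columns \code{subject_id}, \code{family_id},
#'   \code{exam} (integer index, increasing in time), \code{sbp}, \code{dbp},
#'   \code{meds}, \code{sex}, \code{smoke}, \code{age}. Extra columns are
#'   carried through. Column names can be remapped via \code{col_map}.
#' @param col_map optional named character vector mapping the canonical names
#'   to the names used in \code{records}, e.g.
#'   \code{c(subject_id = "IID", sbp = "SBP")}.
#' @return an object of class \code{state_sequences}: a data.frame with the
#'   retained exams, a \code{state} column, sorted by subject and exam, plus
#'   attributes \code{n_subjects} and \code{n_dropped_exams}.
#' @export
build_state_sequences <- function(records, col_map = NULL) {
  records <- as.data.frame(records)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(records))
        stop("column '", col_map[[canon]], "' not found in records")
      names(records)[names(records) == col_map[[canon]]] <- canon
    }
  }
  need <- c("subject_id", "exam", .clinical_vars)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lacks columns: ", paste(miss, collapse = ", "))
  if (!"family_id" %in% names(records)) records$family_id <- records$subject_id
  if (nrow(records) == 0L) {
    out <- cbind(records[0, , drop = FALSE], state = integer(0))
    return(structure(out, class = c("state_sequences", "data.frame"),
                     n_subjects = 0L, n_dropped_exams = 0L))
  }
  dup <- duplicated(records[c("subject_id", "exam")])
  if (any(dup))
    stop("duplicate exam index within subject: ",
         paste(unique(records$subject_id[dup]), collapse = ", "))
  complete <- !Reduce(`|`, lapply(records[.clinical_vars], is.na))
  n_dropped <- sum(!complete)
  kept <- records[complete, , drop = FALSE]
  kept <- kept[order(kept$subject_id, kept$exam), , drop = FALSE]
  kept$state <- if (nrow(kept)) assign_state(kept$sbp, kept$dbp, kept$meds) else integer(0)
  rownames(kept) <- NULL
  structure(kept, class = c("state_sequences", "data.frame"),
            n_subjects = length(unique(kept$subject_id)),
            n_dropped_exams = n_dropped)
}

#' @export
print.state_sequences <- function(x, ...) {
  cat("State sequences: ", attr(x, "n_subjects"), " subjects, ",
      nrow(x), " exams (", attr(x, "n_dropped_exams"),
      " exams dropped for missing clinical data)\n", sep = "")
  cat("State counts:\n")
  print(table(factor(x$state, levels = 1:3)))
  invisible(x)
}
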