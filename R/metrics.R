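#' Dice similarity coefficient
#'
#' Spatial overlap \eqn{2|A \cap B| / (|A| + |B|)} counted over voxels
#' (a voxel belongs to a structure iff its centre is inside — the masks
#' already encode that rule), ranging from 0 (no overlap) to 1 (perfect
#' match). Two empty masks are defined to agree perfectly (DSC 1); one
#' empty mask against a non-empty one gives 0.
#'
#' @param a,b \linkS4class{BinaryMask}s on a common grid
#' @return DSC in [0, 1]
#' @export
dice <- function(a, b) {
  stopifnot(is(a, "BinaryMask"), is(b, "BinaryMask"))
  assertCommonGrid(list(a = a, b = b))
  na <- sum(a@membership)
  nb <- sum(b@membership)
  if (na + nb == 0L) return(1)
  2 * sum(a@membership & b@membership) / (na + nb)
}

#' Structure volume in mm^3
#'
#' Member voxel count times voxel volume; no partial-volume handling, the
#' simplest auditable rule.
#'
#' @param mask a \linkS4class{BinaryMask}
#' @return volume in mm^3 (0 for an empty mask)
#' @export
maskVolume <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  sum(mask@membership) * prod(mask@geometry@spacing)
}

#' Volume ratio of a candidate structure versus a reference
#'
#' @param candidate,reference \linkS4class{BinaryMask}s; the reference
#'   must be non-empty
#' @return \code{maskVolume(candidate) / maskVolume(reference)}
#' @export
volumeRatio <- function(candidate, reference) {
  vref <- maskVolume(reference)
  if (vref == 0) stop("reference mask is empty; volume ratio undefined")
  maskVolume(candidate) / vref
}

#' Evaluate segmentation methods against references, case by case
#'
#' For each case, computes DSC, volume and volume ratio of every method
#' mask against the case reference. A case whose masks are not on a
#' common grid (or whose reference is missing/empty) is skipped with a
#' warning and the batch continues.
#'
#' @param cases list; each element is a list with components
#'   \code{case_id} (string), \code{reference} (\linkS4class{BinaryMask})
#'   and \code{methods} (named list of \linkS4class{BinaryMask}s)
#' @param csvPath optional path; when given, the record table is written
#'   as CSV with header \code{case_id,method,dsc,volume_mm3,volume_ratio}
#' @return data.frame with columns \code{case_id}, \code{method},
#'   \code{dsc}, \code{volume_mm3}, \code{volume_ratio}
#' @seealso [evaluationSummary()]
#' @export
evaluateBatch <- function(cases, csvPath = NULL) {
  rows <- list()
  for (case in cases) {
    cid <- if (!is.null(case$case_id)) case$case_id else "<unnamed>"
    res <- tryCatch({
      if (is.null(case$reference))
        stop("case '", cid, "' has no reference mask")
      ref <- case$reference
      if (!any(membership(ref)))
        stop("case '", cid, "' has an empty reference mask")
      local_rows <- list()
      for (mname in names(case$methods)) {
        m <- case$methods[[mname]]
        local_rows[[mname]] <- data.frame(
          case_id = cid, method = mname,
          dsc = dice(m, ref),
          volume_mm3 = maskVolume(m),
          volume_ratio = volumeRatio(m, ref),
          stringsAsFactors = FALSE)
      }
      do.call(rbind, local_rows)
    }, error = function(e) {
      warning("skipping case '", cid, "': ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(), method = character(),
               dsc = numeric(), volume_mm3 = numeric(),
               volume_ratio = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(csvPath)) write.csv(out, csvPath, row.names = FALSE)
  out
}

#' Per-method summary of an evaluation table
#'
#' @param records data.frame from [evaluateBatch()]
#' @return data.frame with mean and median DSC and volume ratio per method
#' @export
evaluationSummary <- function(records) {
  methods <- unique(records$method)
  out <- lapply(methods, function(m) {
    r <- records[records$method == m, ]
    data.frame(method = m, n_cases = nrow(r),
               mean_dsc = mean(r$dsc), median_dsc = median(r$dsc),
               mean_volume_ratio = mean(r$volume_ratio),
               median_volume_ratio = median(r$volume_ratio),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
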