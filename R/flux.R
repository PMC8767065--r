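# Extracellular-flux (plate respirometry) metrics: blank correction,
# NOCR / basal / maximal / spare capacity, acute responses, normalization.

#' Construct a flux plate
#'
#' Well-by-cycle oxygen consumption rates with an injection schedule and
#' blank flags.
#'
#' @param ocr numeric matrix, wells x cycles (rownames = well ids),
#'   pmol O2/min.
#' @param blank logical vector flagging cell-free blank wells.
#' @param times numeric vector of measurement-cycle mid-times, minutes,
#'   strictly increasing.
#' @param injections data.frame with columns `agent` and `cycle` (first
#'   measurement cycle affected), in injection order.
#' @return an object of class `flux_plate`.
#' @export
flux_plate <- function(ocr, blank, times, injections) {
  if (!is.matrix(ocr)) stop("ocr must be a wells x cycles matrix", call. = FALSE)
  if (is.null(rownames(ocr)))
    rownames(ocr) <- sprintf("W%02d", seq_len(nrow(ocr)))
  if (length(blank) != nrow(ocr))
    stop("blank flags must match the number of wells", call. = FALSE)
  if (length(times) != ncol(ocr))
    stop("cycle times must match the number of cycles", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("cycle times must be strictly increasing", call. = FALSE)
  injections$cycle <- as.integer(injections$cycle)
  if (any(injections$cycle < 1L) || any(injections$cycle > ncol(ocr)))
    stop("schedule error: injection cycle outside the plate", call. = FALSE)
  if (nrow(injections) > 1 && any(diff(injections$cycle) <= 0))
    stop("schedule error: injections must be in increasing cycle order",
         call. = FALSE)
  structure(list(ocr = ocr, blank = as.logical(blank), times = times,
                 injections = injections),
            class = "flux_plate")
}

#' @export
print.flux_plate <- function(x, ...) {
  cat(sprintf("<flux_plate> %d wells (%d blank), %d cycles, injections: %s\n",
              nrow(x$ocr), sum(x$blank), ncol(x$ocr),
              paste(sprintf("%s@%d", x$injections$agent, x$injections$cycle),
                    collapse = ", ")))
  invisible(x)
}

#' Read a flux plate from CSV + YAML
#'
#' @param ocr_path CSV with columns `well, cycle, time_min, ocr` and an
#'   optional logical `blank` column.
#' @param schedule_path YAML mapping agent names to first affected cycle.
#' @param blank_wells character vector of blank well ids (used when the CSV
#'   has no `blank` column).
#' @return a [flux_plate].
#' @export
read_flux_plate <- function(ocr_path, schedule_path, blank_wells = character()) {
  df <- utils::read.csv(ocr_path, stringsAsFactors = FALSE)
  need <- c("well", "cycle", "time_min", "ocr")
  if (!all(need %in% names(df)))
    stop("flux CSV must have columns well, cycle, time_min, ocr", call. = FALSE)
  wells <- unique(df$well)
  cycles <- sort(unique(df$cycle))
  ocr <- matrix(NA_real_, length(wells), length(cycles),
                dimnames = list(wells, NULL))
  ocr[cbind(match(df$well, wells), match(df$cycle, cycles))] <- df$ocr
  if (anyNA(ocr)) stop("missing (well, cycle) OCR values", call. = FALSE)
  times <- vapply(cycles, function(cy) df$time_min[df$cycle == cy][1],
                  numeric(1))
  blank <- if ("blank" %in% names(df)) {
    vapply(wells, function(w) as.logical(df$blank[df$well == w][1]), logical(1))
  } else wells %in% blank_wells
  sched <- yaml::read_yaml(schedule_path)
  injections <- data.frame(agent = names(sched),
                           cycle = as.integer(unlist(sched)))
  injections <- injections[order(injections$cycle), , drop = FALSE]
  flux_plate(ocr, blank, times, injections)
}

#' Write a flux plate to CSV
#'
#' @param plate a [flux_plate].
#' @param path output CSV path (long format, columns
#'   `well, cycle, time_min, ocr, blank`).
#' @export
write_flux_plate <- function(plate, path) {
  df <- expand.grid(well = rownames(plate$ocr),
                    cycle = seq_len(ncol(plate$ocr)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$time_min <- plate$times[df$cycle]
  df$ocr <- plate$ocr[cbind(match(df$well, rownames(plate$ocr)), df$cycle)]
  df$blank <- plate$blank[match(df$well, rownames(plate$ocr))]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Blank-correct a flux plate
#'
#' Subtracts the per-cycle mean of the blank wells from every sample well,
#' removing shared instrument drift (temperature-sensitive fluorophore
#' fluctuations). Blank wells are dropped unless `drop_blanks = FALSE`.
#'
#' @param plate a [flux_plate] with at least one blank well.
#' @param drop_blanks drop the blank wells from the returned plate.
#' @return a corrected [flux_plate].
#' @export
blank_correct <- function(plate, drop_blanks = TRUE) {
  stopifnot(inherits(plate, "flux_plate"))
  if (!any(plate$blank))
    stop("no blank wells: cannot blank-correct", call. = FALSE)
  bl_mean <- colMeans(plate$ocr[plate$blank, , drop = FALSE])
  ocr <- sweep(plate$ocr, 2, bl_mean)
  if (drop_blanks) {
    keep <- !plate$blank
    flux_plate(ocr[keep, , drop = FALSE], plate$blank[keep], plate$times,
               plate$injections)
  } else {
    flux_plate(ocr, plate$blank, plate$times, plate$injections)
  }
}

# Cycle indices of an agent's segment: from its injection cycle up to the
# cycle before the next injection (or the end of the run).
agent_segment <- function(plate, agent) {
  inj <- plate$injections
  j <- match(agent, inj$agent)
  if (is.na(j)) return(NULL)
  from <- inj$cycle[j]
  to <- if (j < nrow(inj)) inj$cycle[j + 1] - 1L else ncol(plate$ocr)
  if (to < from) return(integer())
  seq.int(from, to)
}

find_agent <- function(plate, pattern, label) {
  hit <- grep(pattern, plate$injections$agent, ignore.case = TRUE, value = TRUE)
  if (length(hit) == 0)
    stop(sprintf("missing required injection: %s", label), call. = FALSE)
  hit[1]
}

#' Compute absolute respiration metrics per well
#'
#' NOCR = minimum OCR over cycles after the antimycin A/rotenone injection;
#' basal = mean pre-injection OCR minus NOCR; maximal = maximum OCR over the
#' FCCP segment minus NOCR; spare respiratory capacity (SRC) = maximal -
#' basal. Acute responses (extremum within an agent's segment minus the last
#' pre-injection value) are included for every injected agent.
#'
#' @param plate a (typically blank-corrected) [flux_plate] whose injections
#'   include FCCP and antimycin/rotenone.
#' @return tibble with `well`, `pre_ocr`, `nocr`, `basal`, `maximal`, `src`
#'   and one `acute_<agent>` column per injection.
#' @export
compute_flux_metrics <- function(plate) {
  stopifnot(inherits(plate, "flux_plate"))
  fccp <- find_agent(plate, "fccp", "FCCP")
  antrot <- find_agent(plate, "ant|rot", "antimycin A/rotenone")
  inj <- plate$injections
  first_cycle <- min(inj$cycle)
  if (first_cycle < 2L)
    stop("no pre-injection cycles on this plate", call. = FALSE)
  pre <- seq_len(first_cycle - 1L)
  seg_f <- agent_segment(plate, fccp)
  cyc_ar <- inj$cycle[match(antrot, inj$agent)]
  after_ar <- seq.int(cyc_ar, ncol(plate$ocr))
  keep <- !plate$blank
  ocr <- plate$ocr[keep, , drop = FALSE]
  pre_ocr <- unname(rowMeans(ocr[, pre, drop = FALSE]))
  nocr <- unname(apply(ocr[, after_ar, drop = FALSE], 1, min))
  basal <- pre_ocr - nocr
  maximal <- unname(apply(ocr[, seg_f, drop = FALSE], 1, max)) - nocr
  out <- tibble::tibble(well = rownames(ocr), pre_ocr = pre_ocr,
                        nocr = nocr, basal = basal, maximal = maximal,
                        src = maximal - basal)
  for (ag in inj$agent) {
    ac <- acute_response(plate, ag)
    out[[paste0("acute_", ag)]] <- ac$acute[match(out$well, ac$well)]
  }
  out
}

#' Acute OCR response to an injected agent
#'
#' The extremum of OCR within the agent's segment (the direction with the
#' larger absolute deviation) minus the OCR at the last cycle before the
#' injection.
#'
#' @param plate a [flux_plate].
#' @param agent one of the injected agent names.
#' @return tibble with `well` and `acute` (pmol O2/min; positive = OCR rise).
#' @export
acute_response <- function(plate, agent) {
  seg <- agent_segment(plate, agent)
  if (is.null(seg))
    stop(sprintf("agent '%s' is not among the injections", agent),
         call. = FALSE)
  if (length(seg) == 0)
    stop(sprintf("agent '%s' has an empty segment", agent), call. = FALSE)
  before_cycle <- seg[1] - 1L
  keep <- !plate$blank
  ocr <- plate$ocr[keep, , drop = FALSE]
  before <- unname(ocr[, before_cycle])
  segm <- ocr[, seg, drop = FALSE]
  hi <- unname(apply(segm, 1, max)) - before
  lo <- unname(apply(segm, 1, min)) - before
  acute <- ifelse(abs(hi) >= abs(lo), hi, lo)
  tibble::tibble(well = rownames(ocr), acute = acute)
}

#' Normalize flux metrics
#'
#' Divides every metric by a per-well divisor: the basal respiration
#' (`mode = "basal_respiration"`, so basal maps to 1 and
#' maximal = 1 + SRC exactly) or the raw pre-injection OCR
#' (`mode = "pre_injection_ocr"`). The two conventions differ by whether
#' the non-mitochondrial OCR is subtracted from the divisor; both are
#' provided and recorded in the output.
#'
#' @param metrics tibble from [compute_flux_metrics()].
#' @param mode `"basal_respiration"` or `"pre_injection_ocr"`.
#' @return tibble of the same shape (metric columns divided by the
#'   divisor), with columns `divisor` and `normalization` appended.
#' @export
normalize_to_basal <- function(metrics,
                               mode = c("basal_respiration",
                                        "pre_injection_ocr")) {
  mode <- match.arg(mode)
  div <- switch(mode, basal_respiration = metrics$basal,
                pre_injection_ocr = metrics$pre_ocr)
  if (any(div <= 0))
    stop("normalization divisor must be positive in every well", call. = FALSE)
  out <- metrics
  num_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
                      character())
  for (cn in num_cols) out[[cn]] <- metrics[[cn]] / div
  out$divisor <- div
  out$normalization <- mode
  out
}
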