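# Cross-dataset consensus biomarker sets and the time-invariance rule.

#' Consensus biomarker set across datasets at one exposure style
#'
#' A gene enters the consensus set when it is a DEG (per
#' [test_differential()]) in at least `min_datasets` of the supplied
#' tables, with the same direction in every table where it is a DEG. By
#' default a gene must be a DEG in every dataset in which it is measured
#' (genes absent from a platform are judged on the datasets that carry
#' them).
#'
#' @param deg_tables List of `DegTable`s, one per dataset, all from the
#'   same exposure style.
#' @param min_datasets Minimum number of tables in which a gene must be a
#'   DEG; `NULL` (default) means "every table in which the gene is
#'   measured". `min_datasets = 1` yields the union of per-dataset DEGs
#'   with unanimous directions.
#' @param name,source_exposure Labels attached to the set.
#' @return A `BiomarkerSet`: data frame (gene, direction) with attributes
#'   `name` and `source_exposure`.
#' @export
consensus_set <- function(deg_tables, min_datasets = NULL, name = "consensus",
                          source_exposure = NULL) {
  if (length(deg_tables) < 1L) {
    stop_input("consensus_set: need at least one DegTable")
  }
  if (is.null(source_exposure)) {
    source_exposure <- attr(deg_tables[[1]], "exposure_style") %||% NA
  }
  universe <- sort(unique(unlist(lapply(deg_tables, function(t) t$gene))))
  genes <- character(0)
  dirs <- character(0)
  for (g in universe) {
    present <- 0L
    n_deg <- 0L
    g_dirs <- character(0)
    for (tab in deg_tables) {
      i <- match(g, tab$gene)
      if (is.na(i)) next
      present <- present + 1L
      if (tab$is_deg[i]) {
        n_deg <- n_deg + 1L
        g_dirs <- c(g_dirs, tab$direction[i])
      }
    }
    need <- if (is.null(min_datasets)) present else min_datasets
    if (present == 0L || n_deg < need || n_deg == 0L) next
    if (length(unique(g_dirs)) != 1L) next
    genes <- c(genes, g)
    dirs <- c(dirs, g_dirs[1])
  }
  if (length(genes) == 0L) {
    message("consensus_set: empty intersection at exposure '",
            source_exposure, "'")
  }
  structure(data.frame(gene = genes, direction = dirs,
                       stringsAsFactors = FALSE),
            class = c("BiomarkerSet", "data.frame"),
            name = name, source_exposure = source_exposure)
}

# Direction call for one gene at one exposure, aggregated over that
# exposure's datasets by unanimity on the sign of delta (significance is
# NOT re-required at cross-check exposures; a zero delta evidences no
# direction and counts as disagreement).
direction_call <- function(deltas) {
  if (length(deltas) == 0L) return("absent")
  s <- sign(deltas)
  if (all(s == 1)) return("+")
  if (all(s == -1)) return("-")
  "+/-"
}

#' Cross-exposure modulation table and time-invariance flags
#'
#' For every gene of a consensus set and every exposure style, aggregates
#' a direction call over that exposure's datasets: "+" when the sign of
#' the NGHC-minus-NHC mean difference is positive in every dataset that
#' measures the gene, "-" when negative in all, "+/-" when the datasets
#' disagree (or any delta is exactly zero), and "absent" when no dataset
#' measures it. A gene is time-invariant when its call at every required
#' exposure is "+" or "-" and all the calls are equal.
#'
#' @param consensus A `BiomarkerSet`.
#' @param deg_by_exposure Named list, exposure tag -> list of `DegTable`s.
#' @param required_exposures Exposure tags the invariance rule must cover
#'   (default: all of `names(deg_by_exposure)`).
#' @return A `ModulationTable` data frame: gene, one call column per
#'   exposure, time_invariant.
#' @export
cross_check <- function(consensus, deg_by_exposure,
                        required_exposures = names(deg_by_exposure)) {
  miss <- setdiff(required_exposures, names(deg_by_exposure))
  if (length(miss) > 0L) {
    stop_input("cross_check: no DEG tables for required exposure(s): ",
               paste(miss, collapse = ", "))
  }
  exposures <- names(deg_by_exposure)
  calls <- matrix("absent", nrow = nrow(consensus), ncol = length(exposures),
                  dimnames = list(consensus$gene, exposures))
  for (e in exposures) {
    for (g in consensus$gene) {
      deltas <- numeric(0)
      for (tab in deg_by_exposure[[e]]) {
        i <- match(g, tab$gene)
        if (!is.na(i)) deltas <- c(deltas, tab$delta[i])
      }
      calls[g, e] <- direction_call(deltas)
    }
  }
  out <- data.frame(gene = consensus$gene, calls,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  out$time_invariant <- modulation_flags(calls[, required_exposures,
                                               drop = FALSE])
  structure(out, class = c("ModulationTable", "data.frame"),
            required_exposures = required_exposures,
            source_set = attr(consensus, "name"))
}

#' Apply the time-invariance rule to a matrix of modulation calls
#'
#' @param calls Character matrix or data frame of per-exposure calls in
#'   `{"+", "-", "+/-", "absent"}` (rows = genes, columns = the required
#'   exposures).
#' @return Logical vector: `TRUE` where every call is "+" or every call is
#'   "-"; any "+/-", "absent", or mixture of directions gives `FALSE`.
#' @examples
#' modulation_flags(rbind(c("+", "+", "+"), c("-", "-", "+/-")))
#' @export
modulation_flags <- function(calls) {
  calls <- as.matrix(calls)
  apply(calls, 1, function(row) {
    all(row %in% c("+", "-")) && length(unique(row)) == 1L
  })
}

#' Restrict a modulation table to its time-invariant genes
#'
#' @param modulation A `ModulationTable`.
#' @param consensus The `BiomarkerSet` it was derived from (supplies
#'   directions).
#' @return A `BiomarkerSet` containing only the time-invariant genes.
#' @export
invariant_set <- function(modulation, consensus) {
  keep <- modulation$gene[modulation$time_invariant]
  sub <- consensus[consensus$gene %in% keep, , drop = FALSE]
  rownames(sub) <- NULL
  structure(sub, class = c("BiomarkerSet", "data.frame"),
            name = paste0(attr(consensus, "name"), "_time_invariant"),
            source_exposure = attr(consensus, "source_exposure"))
}

#' Read a modulation-call fixture table
#'
#' Reads a TSV with columns set, gene, per-exposure call columns, and a
#' reference time_invariant column ("Yes"/"No"). The package ships one
#' such fixture in `inst/extdata/modulation_calls.tsv`, encoding the
#' published per-exposure modulation calls of six rat liver NGHC biomarker
#' sets, against which [modulation_flags()] can be replayed.
#'
#' @param path TSV path; default is the shipped fixture.
#' @return Data frame with the call columns as characters.
#' @export
read_modulation_calls <- function(path = system.file(
                                    "extdata", "modulation_calls.tsv",
                                    package = "tinvmark")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  tab
}
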