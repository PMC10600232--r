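# Chromatin-state annotation of ACRs and gene-region/distal classification
# of Quies ACRs.

#' The eight collapsed chromatin states, in tie-break priority order
#'
#' Priority runs from active to quiescent:
#' TssA > Enh > BivR > Tx > ReprPC > Het > ZNF/Rpts > Quies.
#' An ACR overlapping two states by the same number of bases is assigned the
#' higher-priority (earlier) state; an ACR overlapping no segment is Quies.
#'
#' @export
chromatin_states <- function() {
  c("TssA", "Enh", "BivR", "Tx", "ReprPC", "Het", "ZNF/Rpts", "Quies")
}

#' Default 18-state to 8-state collapsing map
#'
#' A Roadmap-style grouping of the 18 expanded-model state labels into the
#' eight collapsed classes used for annotation. Supply your own two-column
#' data.frame (`from`, `to`) to [collapse_states()] if your segmentation uses
#' different labels.
#'
#' @return data.frame with columns `from` (18-state label) and `to`
#'   (collapsed state).
#' @export
default_state_collapse <- function() {
  data.frame(
    from = c("TssA", "TssFlnk", "TssFlnkU", "TssFlnkD",
             "Tx", "TxWk",
             "EnhG1", "EnhG2", "EnhA1", "EnhA2", "EnhWk",
             "ZNF/Rpts", "Het",
             "TssBiv", "EnhBiv",
             "ReprPC", "ReprPCWk",
             "Quies"),
    to = c("TssA", "TssA", "TssA", "TssA",
           "Tx", "Tx",
           "Enh", "Enh", "Enh", "Enh", "Enh",
           "ZNF/Rpts", "Het",
           "BivR", "BivR",
           "ReprPC", "ReprPC",
           "Quies"),
    stringsAsFactors = FALSE
  )
}

#' Collapse segmentation state labels
#'
#' @param segments data.frame with `chrom`, `start`, `end`, `state`.
#' @param map two-column data.frame (`from`, `to`);
#'   defaults to [default_state_collapse()].
#' @return `segments` with `state` replaced by collapsed labels.
#' @export
collapse_states <- function(segments, map = default_state_collapse()) {
  i <- match(segments$state, map$from)
  if (anyNA(i)) {
    stop("no collapse mapping for state label '",
         segments$state[is.na(i)][1L], "'")
  }
  segments$state <- map$to[i]
  segments
}

#' Annotate ACRs with chromatin states
#'
#' Assigns each ACR the collapsed chromatin state with the largest base-pair
#' overlap. Ties go to the higher-priority state (see [chromatin_states()]);
#' ACRs overlapping no segment are Quies.
#'
#' @param acrs data.frame of ACRs with `acr_id`, `chrom`, `start`, `end`.
#' @param segments state segmentation (`chrom`, `start`, `end`, `state`),
#'   non-overlapping within each chromosome, labels drawn from the 8-state
#'   set.
#' @return named character vector, `acr_id` -> state.
#' @export
annotate_states <- function(acrs, segments) {
  states <- chromatin_states()
  bad <- setdiff(unique(segments$state), states)
  if (length(bad)) {
    stop("unknown state label(s): ", paste(bad, collapse = ", "),
         " (collapse with collapse_states() first)")
  }
  check_intervals(segments, "state segment")
  out <- rep("Quies", nrow(acrs))
  names(out) <- acrs$acr_id
  if (nrow(acrs) == 0L || nrow(segments) == 0L) return(out)
  ov <- intervals_overlap(acrs, segments)
  if (nrow(ov) == 0L) return(out)
  # total overlap per (ACR, state): a state may span several segments
  st <- segments$state[ov$subject]
  agg <- stats::aggregate(
    list(overlap = ov$overlap),
    by = list(query = ov$query, state = st), FUN = sum
  )
  prio <- match(agg$state, states)
  # per ACR: largest total overlap wins, ties by state priority
  o <- order(agg$query, -agg$overlap, prio)
  first <- o[!duplicated(agg$query[o])]
  out[agg$query[first]] <- agg$state[first]
  out
}

#' Classify Quies ACRs as gene-region or distal
#'
#' A Quies ACR is in a gene region if it overlaps any gene interval extended
#' by `flank_fraction` of the gene's length on both sides (default 5%);
#' otherwise it is distal. Extended starts are clamped at 0.
#'
#' @param quies_acrs data.frame of ACRs (typically those annotated Quies).
#' @param genes data.frame of gene models.
#' @param flank_fraction fraction of gene length added up- and downstream.
#' @return named character vector, `acr_id` -> `"gene_region"` or
#'   `"distal"`.
#' @export
classify_quies_context <- function(quies_acrs, genes, flank_fraction = 0.05) {
  stopifnot(flank_fraction >= 0)
  out <- rep("distal", nrow(quies_acrs))
  names(out) <- quies_acrs$acr_id
  if (nrow(quies_acrs) == 0L || nrow(genes) == 0L) return(out)
  flank <- floor(flank_fraction * (genes$end - genes$start))
  ext <- data.frame(chrom = genes$chrom,
                    start = pmax(0, genes$start - flank),
                    end = genes$end + flank)
  ov <- intervals_overlap(quies_acrs, ext)
  out[unique(ov$query)] <- "gene_region"
  out
}
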