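#' @include binnedGenome.R
NULL

#' Construct a ScoreTrack
#'
#' @param binTable a \linkS4class{BinnedGenome}.
#' @param values numeric, one per bin.
#' @param kind track kind (see \linkS4class{ScoreTrack}).
#' @param window window half-width in bins, if applicable.
#' @param channel source channel, if applicable.
#' @return a \linkS4class{ScoreTrack}.
#' @export
scoreTrack <- function(binTable, values, kind = "other",
                       window = NA_integer_, channel = NA_character_) {
    new("ScoreTrack", binTable = binTable, values = as.numeric(values),
        kind = kind, window = as.integer(window), channel = channel)
}

#' @rdname accessors
#' @export
setMethod("values", "ScoreTrack", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("bins", "ScoreTrack", function(x) x@binTable@bins)
#' @rdname accessors
#' @export
setMethod("nbins", "ScoreTrack", function(x) length(x@binTable@bins))
#' @rdname accessors
#' @export
setMethod("trackKind", "ScoreTrack", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("channel", "ScoreTrack", function(x) x@channel)

setMethod("show", "ScoreTrack", function(object) {
    v <- object@values
    cat(sprintf("ScoreTrack [%s]: %d bins, %d defined, range [%.3g, %.3g]\n",
                object@kind, length(v), sum(!is.na(v)),
                suppressWarnings(min(v, na.rm = TRUE)),
                suppressWarnings(max(v, na.rm = TRUE))))
})

#' Convert a ScoreTrack to a GRanges
#'
#' Bins with missing values are dropped; the value lands in the
#' \code{score} column (ready for bedGraph export).
#'
#' @param track a \linkS4class{ScoreTrack}.
#' @return a \code{GRanges} with a \code{score} column.
#' @export
trackAsGRanges <- function(track) {
    keep <- !is.na(track@values)
    gr <- track@binTable@bins[keep]
    S4Vectors::mcols(gr)$score <- track@values[keep]
    gr
}

#' Write a ScoreTrack as bedGraph
#'
#' @param track a \linkS4class{ScoreTrack}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTrackBedGraph <- function(track, path) {
    rtracklayer::export.bedGraph(trackAsGRanges(track), path)
    invisible(path)
}

#' Read a bedGraph file as a ScoreTrack
#'
#' Values are assigned to the bins their intervals cover (an interval
#' spanning several bins sets each; bins not covered stay missing).
#'
#' @param path bedGraph file.
#' @param binTable the target \linkS4class{BinnedGenome}.
#' @param kind track kind.
#' @return a \linkS4class{ScoreTrack}.
#' @export
readTrackBedGraph <- function(path, binTable, kind = "other") {
    gr <- rtracklayer::import.bedGraph(path)
    v <- rep(NA_real_, length(binTable@bins))
    hits <- GenomicRanges::findOverlaps(binTable@bins, gr)
    v[S4Vectors::queryHits(hits)] <-
        S4Vectors::mcols(gr)$score[S4Vectors::subjectHits(hits)]
    scoreTrack(binTable, v, kind = kind)
}
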