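#' Summarize replicate activity measurements
#'
#' Collapses the raw replicate activities of one gene under one condition
#' into the four summaries the algorithm uses. Expression replicates are
#' close to log-normal, so the noise statistics are computed on natural
#' logs: the log-SE feeds the two-sample Z value behind the P-score.
#'
#' @param values numeric vector of at least 2 strictly positive replicate
#'   activities.
#' @return named numeric vector: \code{mean} (arithmetic mean of the raw
#'   values), \code{logMean} (mean of natural logs), \code{logSE} (sample
#'   SD of the logs divided by sqrt of the replicate count), \code{n}.
#' @examples
#' summarizeReplicates(c(1, exp(2)))  # logMean 1, logSE 1
#' @export
summarizeReplicates <- function(values) {
    values <- as.numeric(values)
    if (length(values) < 2L)
        stop("need at least 2 replicates, got ", length(values))
    if (any(!is.finite(values) | values <= 0))
        stop("non-positive activity: replicate values must be > 0")
    lv <- log(values)
    c(mean = mean(values),
      logMean = mean(lv),
      logSE = sd(lv) / sqrt(length(values)),
      n = length(values))
}
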