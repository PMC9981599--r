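# 32-channel Biosemi 10-20 layout with approximate 2D head coordinates
# (x towards the right ear, y towards the nose, unit head radius).
.biosemi32 <- data.frame(
  label = c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3", "CP1", "CP5",
            "P7", "P3", "Pz", "PO3", "O1", "Oz", "O2", "PO4", "P4", "P8",
            "CP6", "CP2", "C4", "T8", "FC6", "FC2", "F4", "F8", "AF4", "Fp2",
            "Fz", "Cz"),
  x = c(-0.309, -0.350, -0.809, -0.450, -0.200, -0.650, -1.000, -0.500,
        -0.200, -0.650, -0.809, -0.450, 0.000, -0.350, -0.309, 0.000,
        0.309, 0.350, 0.450, 0.809, 0.650, 0.200, 0.500, 1.000, 0.650,
        0.200, 0.450, 0.809, 0.350, 0.309, 0.000, 0.000),
  y = c(0.951, 0.820, 0.588, 0.550, 0.300, 0.300, 0.000, 0.000, -0.300,
        -0.300, -0.588, -0.550, -0.500, -0.820, -0.951, -1.000, -0.951,
        -0.820, -0.550, -0.588, -0.300, -0.300, 0.000, 0.000, 0.300,
        0.300, 0.550, 0.588, 0.820, 0.951, 0.500, 0.000),
  stringsAsFactors = FALSE
)

#' Standard 32-channel montage
#'
#' Channel labels and approximate 2D scalp coordinates for the 32-channel
#' Biosemi 10-20 layout used throughout the package.
#'
#' @return data.frame with columns `label`, `x`, `y`
#' @export
biosemi_montage <- function() .biosemi32

#' Electrode sets used by the analyses
#'
#' `occipital_cluster()` returns the five parietal/occipital electrodes over
#' which event-locked ERPs and ITC are averaged; `central_channels()` returns
#' the vertex pair used for the non-event-locked inter-brain measures.
#'
#' @return character vector of channel labels
#' @export
occipital_cluster <- function() c("PO3", "PO4", "O1", "Oz", "O2")

#' @rdname occipital_cluster
#' @export
central_channels <- function() c("C3", "C4")

#' Frontal channels receiving simulated saccade transients
#' @return character vector of channel labels
#' @keywords internal
frontal_channels <- function() c("Fp1", "Fp2", "AF3", "AF4")

# k nearest channels (by 2D distance) to `label` among `candidates`
nearest_channels <- function(label, candidates, k = 4) {
  m <- .biosemi32
  i <- match(label, m$label)
  j <- match(candidates, m$label)
  if (is.na(i) || anyNA(j)) return(head(candidates, k))
  d <- sqrt((m$x[j] - m$x[i])^2 + (m$y[j] - m$y[i])^2)
  candidates[order(d)][seq_len(min(k, length(candidates)))]
}
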