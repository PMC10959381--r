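#' Load the model atlas of identifiable head neurons
#'
#' The package ships an approximate, editable table of 21 head-neuron classes
#' whose stereotyped activity supports identification: the backward-locomotion
#' group (AVA, AVE, AIB, RIM pairs and the VA01/DA01 motor neurons) and the
#' forward-locomotion group (AVB, RIB, RME classes, RID, RIS, DB01). The
#' positions are synthetic approximations of the stereotyped arrangement (x
#' anterior, y dorsal, z left), not measurements; they are intended as a
#' starting point to be replaced or edited for a given strain or setup.
#'
#' On load, coordinates are normalized to the convention used throughout
#' identification: the origin is the mean position of the six seed neurons
#' (AVAL/R, AVEL/R, AIBL/R) and the unit length is their mean pairwise
#' distance.
#'
#' @param path CSV with columns `(class_name, x, y, z, group, side)`;
#'   defaults to the shipped table.
#' @return data frame of atlas neurons in normalized coordinates.
#' @export
default_atlas <- function(path = system.file("extdata", "atlas.csv",
                                             package = "nematrace")) {
  a <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("class_name", "x", "y", "z", "group", "side")
  if (!all(need %in% names(a)))
    stop("atlas must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(a$class_name)) stop("atlas class names must be unique")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    stop("atlas positions must be finite")
  seed <- seed_six_classes()
  if (!all(seed %in% a$class_name))
    stop("atlas must contain the six seed classes: ",
         paste(seed, collapse = ", "))
  p <- as.matrix(a[, c("x", "y", "z")])
  sp <- p[match(seed, a$class_name), , drop = FALSE]
  ctr <- colMeans(sp)
  scale <- pairwise_mean_distance(sp)
  p <- sweep(p, 2, ctr) / scale
  a$x <- p[, 1]; a$y <- p[, 2]; a$z <- p[, 3]
  a
}

#' The six seed classes anchoring identification
#'
#' The AVA, AVE and AIB pairs: bilateral backward-command neurons whose high
#' mutual activity correlation and roughly collinear arrangement along the
#' anteroposterior axis anchor the body coordinate frame.
#'
#' @return character vector of six class names.
#' @export
seed_six_classes <- function() {
  c("AVAL", "AVAR", "AVEL", "AVER", "AIBL", "AIBR")
}
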