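#' Design of a clustered pacing study
#'
#' Describes the factorial layout of the mapping study: animals nested in
#' class (control vs persistent AF), crossed with 4 pacing positions and 2
#' train levels (S1, S2), with a between-animal random intercept and known
#' fixed effects per cell. The default layout mirrors a 7-animal study
#' (3 control, 4 persistent AF) with one missing observation, giving
#' 7 x 4 x 2 - 1 = 55 rows.
#'
#' @param n_control,n_af number of animals per class.
#' @param positions pacing positions (default top/bottom/left/right).
#' @param trains train levels (default S1, S2).
#' @param grand_mean outcome grand mean.
#' @param class_effect additive shift for persistent-AF animals.
#' @param train_effect additive shift for S2 beats (both classes).
#' @param position_effects named numeric vector of additive shifts per
#'   position (missing positions get 0).
#' @param class_train_effect extra S2 shift specific to persistent-AF
#'   animals (the class x train interaction).
#' @param class_position_effects named numeric vector: extra per-position
#'   shifts specific to persistent-AF animals.
#' @param animal_sd between-animal random-intercept SD (>= 0).
#' @param resid_sd residual SD (>= 0).
#' @param missing list of cells to drop, each
#'   `list(animal = "AF2", position = "right", train = "S2")`. Cells must
#'   exist in the full factorial. Default drops one S2 observation,
#'   reproducing the published 55-row layout.
#' @param seed RNG seed.
#' @return an object of class `study_design`.
#' @seealso [make_study_table()]
#' @export
study_design <- function(n_control = 3L, n_af = 4L,
                         positions = c("top", "bottom", "left", "right"),
                         trains = c("S1", "S2"),
                         grand_mean = 20, class_effect = 20,
                         train_effect = 2, position_effects = NULL,
                         class_train_effect = 10,
                         class_position_effects = NULL,
                         animal_sd = 4.26, resid_sd = 5,
                         missing = list(list(animal = "AF2",
                                             position = "right",
                                             train = "S2")),
                         seed = 1L) {
  if (n_control < 1L || n_af < 1L) stop("need at least one animal per class", call. = FALSE)
  if (animal_sd < 0 || resid_sd < 0) stop("SDs must be non-negative", call. = FALSE)
  if (length(positions) < 1L || length(trains) < 1L)
    stop("positions and trains must be non-empty", call. = FALSE)
  animals <- c(paste0("C", seq_len(n_control)), paste0("AF", seq_len(n_af)))
  for (cell in missing) {
    if (!cell$animal %in% animals || !cell$position %in% positions ||
        !cell$train %in% trains)
      stop("missing cell not part of the full factorial: ",
           paste(cell$animal, cell$position, cell$train), call. = FALSE)
  }
  pe <- stats::setNames(rep(0, length(positions)), positions)
  if (!is.null(position_effects)) pe[names(position_effects)] <- position_effects
  cpe <- stats::setNames(rep(0, length(positions)), positions)
  if (!is.null(class_position_effects))
    cpe[names(class_position_effects)] <- class_position_effects
  structure(list(
    n_control = as.integer(n_control), n_af = as.integer(n_af),
    animals = animals,
    classes = stats::setNames(rep(c("control", "persistentAF"),
                                  c(n_control, n_af)), animals),
    positions = positions, trains = trains,
    grand_mean = grand_mean, class_effect = class_effect,
    train_effect = train_effect, position_effects = pe,
    class_train_effect = class_train_effect, class_position_effects = cpe,
    animal_sd = animal_sd, resid_sd = resid_sd,
    missing = missing, seed = as.integer(seed)
  ), class = "study_design")
}

#' Simulate a clustered study table
#'
#' Draws one outcome per retained (animal, position, train) cell:
#' grand mean + class/train/position effects + interactions + a per-animal
#' random intercept (SD `animal_sd`) + residual noise (SD `resid_sd`).
#' Reproducible for a fixed seed.
#'
#' @param design a [study_design()].
#' @param outcome name for the outcome column (default `"outcome"`).
#' @return a data.frame with columns `animal`, `class`, `position`, `train`
#'   and the outcome, one row per retained cell.
#' @export
make_study_table <- function(design, outcome = "outcome") {
  stopifnot(inherits(design, "study_design"))
  tab <- expand.grid(animal = design$animals, position = design$positions,
                     train = design$trains, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  if (nrow(tab) == 0L) stop("empty design", call. = FALSE)
  drop <- rep(FALSE, nrow(tab))
  for (cell in design$missing) {
    drop <- drop | (tab$animal == cell$animal &
                    tab$position == cell$position &
                    tab$train == cell$train)
  }
  tab <- tab[!drop, , drop = FALSE]
  tab$class <- unname(design$classes[tab$animal])

  set.seed(design$seed)
  animal_re <- stats::setNames(
    stats::rnorm(length(design$animals), sd = design$animal_sd),
    design$animals
  )
  is_af <- tab$class == "persistentAF"
  is_s2 <- tab$train == "S2"
  mu <- design$grand_mean +
    design$class_effect * is_af +
    design$train_effect * is_s2 +
    design$position_effects[tab$position] +
    design$class_train_effect * (is_af & is_s2) +
    design$class_position_effects[tab$position] * is_af
  tab[[outcome]] <- unname(mu) + unname(animal_re[tab$animal]) +
    stats::rnorm(nrow(tab), sd = design$resid_sd)

  tab <- tab[order(tab$animal, tab$position, tab$train),
             c("animal", "class", "position", "train", outcome)]
  rownames(tab) <- NULL
  tab
}
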