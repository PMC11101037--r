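# 66-point facial landmark layout (DISFA-style AAM markup, 0-based indices):
#   0-16 jawline, 17-26 brows, 27-35 nose, 36-47 eyes, 48-65 lips.
# Coordinates use the image convention: x grows rightward, y grows downward.

KEYPOINT_N <- 66L
KPM_DIM <- 132L

# The 12 coded action units, in file-column order.
AU_IDS <- c(1L, 2L, 4L, 5L, 6L, 9L, 12L, 15L, 17L, 20L, 25L, 26L)

# Six anchors used for whole-face affine registration (0-based).
AFFINE_ANCHORS <- c(0L, 16L, 39L, 42L, 27L, 33L)

# Bilateral left/right landmark pairing for the 66-point layout. This is the
# 68-point iBUG pairing with the two inner lip corners removed (66-point
# indices 60..65 are the inner-lip points 61,62,63,65,66,67 of the 68 markup).
FACE_PAIRS <- rbind(
  c(0L, 16L), c(1L, 15L), c(2L, 14L), c(3L, 13L), c(4L, 12L), c(5L, 11L),
  c(6L, 10L), c(7L, 9L),
  c(17L, 26L), c(18L, 25L), c(19L, 24L), c(20L, 23L), c(21L, 22L),
  c(31L, 35L), c(32L, 34L),
  c(36L, 45L), c(37L, 44L), c(38L, 43L), c(39L, 42L), c(40L, 47L), c(41L, 46L),
  c(48L, 54L), c(49L, 53L), c(50L, 52L), c(55L, 59L), c(56L, 58L),
  c(60L, 62L), c(63L, 65L)
)

# Landmarks lying on the facial midline.
FACE_MIDLINE <- c(8L, 27L, 28L, 29L, 30L, 33L, 51L, 57L, 61L, 64L)

# Outer eye corners define the in-plane roll axis.
EYE_CORNER_R <- 36L
EYE_CORNER_L <- 45L

landmark_colnames <- function() {
  c("frame", paste0("x_", 0:65), paste0("y_", 0:65))
}

au_colnames <- function() c("frame", paste0("AU", AU_IDS))

# Convert one 132-long coordinate row (x_0..x_65, y_0..y_65) to a 66 x 2
# matrix and back.
row_to_xy <- function(row) cbind(row[1:66], row[67:132])
xy_to_row <- function(xy) c(xy[, 1], xy[, 2])

#' Default face part map for part-wise similarity registration
#'
#' Partitions the 66 landmarks into face parts, each with the fixed anchor
#' landmarks used to estimate its similarity transform. Lips have no stable
#' anchors and are exempted from part-wise registration.
#'
#' @return A named list; each element has integer vectors `members` and
#'   `anchors` holding 0-based landmark indices.
#' @export
face_part_map <- function() {
  list(
    right_brow_eye = list(members = c(17:21, 36:41), anchors = c(36L, 39L)),
    left_brow_eye  = list(members = c(22:26, 42:47), anchors = c(42L, 45L)),
    nose           = list(members = 27:35,           anchors = 27L),
    jawline        = list(members = 0:16,            anchors = c(0L, 16L)),
    lips           = list(members = 48:65,           anchors = integer(0))
  )
}

validate_part_map <- function(parts) {
  crm_assert(is.list(parts) && length(parts) > 0, "part map must be a non-empty list")
  all_members <- unlist(lapply(parts, `[[`, "members"))
  crm_assert(!anyDuplicated(all_members), "part members must not overlap")
  crm_assert(all(all_members %in% 0:65), "part members must be 0-based indices in 0..65")
  for (nm in names(parts)) {
    p <- parts[[nm]]
    crm_assert(all(p$anchors %in% 0:65),
               sprintf("anchors of part '%s' out of range", nm))
  }
  invisible(parts)
}
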