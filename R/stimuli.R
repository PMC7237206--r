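#' Build the abstract stimulus catalog
#'
#' Constructs the image catalog used by the scheduler: 129 "main" images
#' (room x painting pairings) plus 12 stay/switch cue images, 141 unique
#' images in total, and 20 base sets of 7 images each (base, art match, room
#' match, 4 distractors). Identifiers are abstract; no image files exist.
#'
#' The main set pairs 40 main rooms with 40 main paintings so that every room
#' and every painting appears in 3 images (120 pairings, of which 3 are
#' dropped), and then adds 12 pairings that reuse the task-irrelevant half of
#' each cue: each of the 3 room backgrounds appearing in art stay/switch cues
#' is also paired with 2 main paintings, and each of the 3 paintings embedded
#' in room stay/switch cues is also paired with 2 main rooms. The cue images
#' themselves pair the art stay and art switch cue paintings with the same 3
#' background rooms, and the room stay and room switch cue rooms with the
#' same 3 embedded paintings, so the irrelevant half of a cue image is never
#' diagnostic of its identity.
#'
#' An art match is another catalog image containing the same painting
#' identity (same artist/style); a room match is another image containing the
#' same room identity (same layout from a different viewpoint). Base images
#' have pairwise distinct rooms and paintings and are never reused as matches
#' or distractors in other sets.
#'
#' @param rng_seed integer seed; the same seed reproduces the catalog
#'   bit-for-bit, different seeds give the same counts with different
#'   pairings.
#' @param n_base_sets number of base sets to construct (default 20).
#' @return a [StimulusCatalog-class].
#' @examples
#' cat20 <- buildStimulusSet(0)
#' nrow(cat20@images)  # 141
#' @export
buildStimulusSet <- function(rng_seed = 0L, n_base_sets = 20L) {
  withSeed(childSeed(rng_seed, "catalog"), {
    rooms <- sprintf("room%02d", 1:40)
    paints <- sprintf("art%02d", 1:40)
    # seeded relabeling makes the pairings seed-dependent
    rooms <- sample(rooms)
    paints <- sample(paints)

    # 3-regular bipartite pairing: room i with paintings i, i+13, i+27 (mod 40)
    core <- do.call(rbind, lapply(1:40, function(i) {
      js <- ((i - 1 + c(0L, 13L, 27L)) %% 40L) + 1L
      data.frame(room_id = rooms[i], painting_id = paints[js],
                 stringsAsFactors = FALSE)
    }))
    # drop 3 pairings with distinct rooms and distinct paintings (keeps every
    # room/painting at degree >= 2, so matches always exist)
    repeat {
      drop <- sample(nrow(core), 3L)
      if (length(unique(core$room_id[drop])) == 3L &&
          length(unique(core$painting_id[drop])) == 3L) break
    }
    core <- core[-drop, ]

    # cue elements
    bg_rooms <- sprintf("cueroom%02d", 1:3)         # backgrounds of art cues
    emb_paints <- sprintf("cueart%02d", 1:3)        # embedded in room cues
    cue_paint <- c(art_stay = "artcue_stay", art_switch = "artcue_switch")
    cue_room <- c(room_stay = "roomcue_stay", room_switch = "roomcue_switch")

    # reuse images: irrelevant halves of cues each appear in 2 main images
    reuse <- rbind(
      do.call(rbind, lapply(bg_rooms, function(r) {
        data.frame(room_id = r, painting_id = sample(paints, 2L),
                   stringsAsFactors = FALSE)
      })),
      do.call(rbind, lapply(emb_paints, function(p) {
        data.frame(room_id = sample(rooms, 2L), painting_id = p,
                   stringsAsFactors = FALSE)
      }))
    )

    main <- rbind(core, reuse)
    main$cue_role <- "none"

    cues <- rbind(
      data.frame(room_id = bg_rooms, painting_id = cue_paint[["art_stay"]],
                 cue_role = "art_stay", stringsAsFactors = FALSE),
      data.frame(room_id = bg_rooms, painting_id = cue_paint[["art_switch"]],
                 cue_role = "art_switch", stringsAsFactors = FALSE),
      data.frame(room_id = cue_room[["room_stay"]], painting_id = emb_paints,
                 cue_role = "room_stay", stringsAsFactors = FALSE),
      data.frame(room_id = cue_room[["room_switch"]], painting_id = emb_paints,
                 cue_role = "room_switch", stringsAsFactors = FALSE)
    )

    images <- rbind(main, cues)
    images$image_id <- ifelse(
      images$cue_role == "none",
      paste0("img_", images$room_id, "_", images$painting_id),
      paste0(images$cue_role, "_", seq_len(nrow(images)) -
               match(images$cue_role, images$cue_role) + 1L))
    # cue image ids: role + 1..3 within role
    for (role in c("art_stay", "art_switch", "room_stay", "room_switch")) {
      k <- images$cue_role == role
      images$image_id[k] <- paste0(role, "_", seq_len(sum(k)))
    }
    rownames(images) <- NULL
    images <- images[, c("image_id", "painting_id", "room_id", "cue_role")]

    base_sets <- .buildBaseSets(images, core, n_base_sets)

    new("StimulusCatalog", images = images, base_sets = base_sets,
        seed = as.integer(rng_seed))
  })
}

.buildBaseSets <- function(images, core, n_base_sets) {
  core_ids <- paste0("img_", core$room_id, "_", core$painting_id)
  main <- images[images$cue_role == "none", ]
  # bases: core images with pairwise distinct rooms and paintings
  ord <- sample(seq_along(core_ids))
  bases <- character(0); used_r <- character(0); used_p <- character(0)
  for (i in ord) {
    if (core$room_id[i] %in% used_r || core$painting_id[i] %in% used_p) next
    bases <- c(bases, core_ids[i])
    used_r <- c(used_r, core$room_id[i])
    used_p <- c(used_p, core$painting_id[i])
    if (length(bases) == n_base_sets) break
  }
  if (length(bases) < n_base_sets) {
    stopf("could not select %d base images with distinct rooms/paintings",
          n_base_sets)
  }
  sets <- lapply(seq_along(bases), function(k) {
    b <- main[main$image_id == bases[k], ]
    am_pool <- main$image_id[main$painting_id == b$painting_id &
                               main$room_id != b$room_id]
    rm_pool <- main$image_id[main$room_id == b$room_id &
                               main$painting_id != b$painting_id]
    am_pool <- setdiff(am_pool, bases)
    rm_pool <- setdiff(rm_pool, bases)
    if (!length(am_pool) || !length(rm_pool)) {
      stopf("no art/room match available for base %s", b$image_id)
    }
    am <- sample(am_pool, 1L)
    rm_ <- sample(rm_pool, 1L)
    d_pool <- main$image_id[main$room_id != b$room_id &
                              main$painting_id != b$painting_id]
    d_pool <- setdiff(d_pool, c(bases, am, rm_))
    ds <- sample(d_pool, 4L)
    data.frame(base_set_id = sprintf("bs%02d", k), base = b$image_id,
               art_match = am, room_match = rm_,
               distractor_1 = ds[1], distractor_2 = ds[2],
               distractor_3 = ds[3], distractor_4 = ds[4],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, sets)
}
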