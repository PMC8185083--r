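#' Default TMTpro 16-plex channel roles
#'
#' The 126 channel carries the booster (carrier) peptide pool and the 127C
#' channel is left empty because it receives isotopic-impurity bleed from the
#' adjacent booster; the remaining fourteen channels hold single cells.
#'
#' @return A tibble with columns `channel` and `role`
#'   (`booster`/`empty`/`single_cell`).
#' @export
default_channels <- function() {
  tibble(
    channel = TMTPRO16,
    role = dplyr::case_when(
      TMTPRO16 == "126" ~ "booster",
      TMTPRO16 == "127C" ~ "empty",
      TRUE ~ "single_cell"
    )
  )
}

.check_channels <- function(channels) {
  channels <- as_tibble(channels)
  stopifnot(all(c("channel", "role") %in% names(channels)))
  bad <- setdiff(unique(channels$role), c("booster", "reference", "empty", "single_cell"))
  if (length(bad)) abort(paste0("Unknown channel role(s): ", paste(bad, collapse = ", ")))
  if (sum(channels$role == "booster") != 1) {
    abort("Exactly one booster channel is required per sample file.")
  }
  channels
}

# Group sizes as even as possible: remainder goes to the first populations.
.balanced_sizes <- function(n, k) {
  base <- n %/% k
  base + as.integer(seq_len(k) <= n %% k)
}

#' Build a plate sort/label layout
#'
#' Partitions a multiwell plate into contiguous blocks of one well per TMT
#' channel; each block is pooled into one multiplexed LC-MS sample. Wells are
#' taken column-major (A1, B1, ... then A2, ...), so on the default 16 x 24
#' plate each column is one block and the plate yields 24 samples. Wells
#' assigned to the booster and empty channels are left unsorted, giving 14
#' single cells per block (336 per default plate). In balanced mode the
#' single-cell channels are split across populations as evenly as possible
#' (14 channels over 3 populations gives groups of 5, 5 and 4) and the
#' channel-to-well assignment is randomized within each block.
#'
#' @param rows,cols Plate shape (default 16 x 24 = 384 wells).
#' @param channels Tibble of `channel`, `role` as from [default_channels()].
#' @param populations Character vector of population labels to sort.
#' @param balanced Distribute populations evenly across single-cell channels
#'   (default `TRUE`); otherwise populations are sampled uniformly per well.
#' @param seed Integer seed; layouts are deterministic given the seed.
#' @param plate_id Plate identifier stamped on every well.
#' @return A `plate_layout` tibble with one row per well: `plate_id`,
#'   `sample_id`, `block`, `well`, `well_row`, `well_col`, `channel`,
#'   `channel_role`, `sorted`, `population`.
#' @export
build_plate_layout <- function(rows = 16, cols = 24,
                               channels = default_channels(),
                               populations = c("LSC", "Progenitor", "Blast"),
                               balanced = TRUE, seed = 1,
                               plate_id = "plate1") {
  channels <- .check_channels(channels)
  n_ch <- nrow(channels)
  n_wells <- rows * cols
  if (n_wells %% n_ch != 0) {
    abort(sprintf("Plate of %d wells cannot be split into blocks of %d channels.",
                  n_wells, n_ch))
  }
  sc_channels <- channels$channel[channels$role == "single_cell"]
  if (length(populations) > length(sc_channels)) {
    abort("More populations than single-cell channels.")
  }
  n_blocks <- n_wells %/% n_ch
  set.seed(seed)

  well_row <- rep(seq_len(rows), times = cols)
  well_col <- rep(seq_len(cols), each = rows)
  block <- rep(seq_len(n_blocks), each = n_ch)

  blocks <- lapply(seq_len(n_blocks), function(b) {
    ch <- if (balanced) sample(channels$channel) else channels$channel
    role <- channels$role[match(ch, channels$channel)]
    pop <- rep(NA_character_, n_ch)
    is_sc <- role == "single_cell"
    if (balanced) {
      sizes <- .balanced_sizes(sum(is_sc), length(populations))
      pop[is_sc] <- sample(rep(populations, sizes))
    } else {
      pop[is_sc] <- sample(populations, sum(is_sc), replace = TRUE)
    }
    tibble(channel = ch, channel_role = role, population = pop)
  })
  assign <- dplyr::bind_rows(blocks)

  layout <- tibble(
    plate_id = plate_id,
    sample_id = sprintf("%s_S%02d", plate_id, block),
    block = block,
    well = paste0(LETTERS[well_row], well_col),
    well_row = LETTERS[well_row],
    well_col = well_col,
    channel = assign$channel,
    channel_role = assign$channel_role,
    sorted = assign$channel_role == "single_cell",
    population = assign$population
  )
  structure(layout,
            class = c("plate_layout", class(layout)),
            rows = rows, cols = cols, seed = seed, balanced = balanced)
}

#' Summarise a plate layout
#'
#' @param x A `plate_layout`.
#' @param ... Unused.
#' @return A one-row tibble: number of sample blocks, single-cell wells,
#'   unsorted wells and populations.
#' @method glance plate_layout
#' @export
glance.plate_layout <- function(x, ...) {
  tibble(
    n_blocks = length(unique(x$block)),
    n_single_cell_wells = sum(x$sorted),
    n_unsorted_wells = sum(!x$sorted),
    n_populations = length(unique(x$population[!is.na(x$population)]))
  )
}

#' Read / write a layout TSV
#'
#' @param x A `plate_layout`.
#' @param path TSV file path.
#' @export
write_layout <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  df <- as_tibble(read.delim(path, check.names = FALSE))
  needed <- c("plate_id", "sample_id", "block", "well", "well_row", "well_col",
              "channel", "channel_role", "sorted", "population")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort(paste0("Layout file lacks column(s): ", paste(missing, collapse = ", ")))
  }
  df$channel <- as.character(df$channel)
  df$population <- as.character(df$population)
  structure(df, class = c("plate_layout", class(df)))
}
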