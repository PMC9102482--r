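#' Cartesian set-points of the machine states
#'
#' The eight motion states of the command machine and the desired
#' end-effector position each one emits, in meters, together with the input
#' code attached to each state and the motion it represents.
#'
#' @return A tibble with columns `state`, `input`, `px`, `py`, `pz`,
#'   `movement`.
#' @export
#' @examples
#' state_targets()
state_targets <- function() {
  tibble::tribble(
    ~state, ~input, ~px, ~py, ~pz, ~movement,
    "S1", "IN1", 0, -0.34, 0.38, "Stop",
    "S2", "IN2", 0, -0.11, 0.46, "Up",
    "S3", "IN4", 0.34, -0.34, 0.38, "Right",
    "S4", "IN7", -0.34, -0.34, 0.38, "Left",
    "DUL", "IN8", -0.34, -0.11, 0.46, "Diagonal Up Left",
    "DUR", "IN3", 0.34, -0.11, 0.46, "Diagonal Up Right",
    "DDL", "IN6", -0.34, -0.34, 0.28, "Diagonal Down Left",
    "DDR", "IN5", 0.34, -0.34, 0.28, "Diagonal Down Right"
  )
}

#' Encode a contraction class as the machine input word
#'
#' Bit order is `[NIM, SMP3, SMP5, SMP]` from most to least significant, so
#' NIM is `"1000"`, SMP3 `"0100"`, SMP5 `"0010"`, SMP `"0001"`. The NIM word
#' is the deactivation input (code IN9).
#'
#' @param class A class name.
#' @return A 4-character bit string; attribute `code` carries `"IN9"` for NIM.
#' @export
#' @examples
#' encode_inputs("SMP3")
encode_inputs <- function(class) {
  class_label(class) # validates
  word <- c(NIM = "1000", SMP3 = "0100", SMP5 = "0010", SMP = "0001")[[class]]
  if (class == "NIM") attr(word, "code") <- "IN9"
  word
}

#' Default transition table of the command machine
#'
#' Loaded from the versioned JSON asset shipped with the package. For each
#' motion state, an SMP event returns to S1 (Stop); SMP3 toggles the vertical
#' component (up-states step back down, down-states step up, and a second
#' SMP3 from an up-diagonal reaches the corresponding down-diagonal); SMP5
#' cycles the horizontal component right-then-left. NIM is not in the table:
#' from any state it forces HOME (deactivated).
#'
#' @param path Optional path to an alternative JSON table
#'   (`{state: {class: next_state}}`).
#' @return A named list: `table[[state]][[class]] -> next state`.
#' @export
#' @examples
#' transition_table()[["S1"]]
transition_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "transition_table.json",
      package = "myohmi", mustWork = TRUE
    )
  }
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- purrr::map(tab, as.list)
  states <- state_targets()$state
  stopifnot(all(states %in% names(tab)))
  tab
}

#' Create the command state machine
#'
#' A Mealy machine: given the current state and a classified contraction
#' event it transitions and emits the destination state's Cartesian
#' set-point. It starts at S1 (Stop), active. A NIM event from any state
#' moves to HOME and deactivates the machine; while deactivated every input
#' is ignored (with a warning) until [fsm_reset()] is called.
#'
#' @param table A transition table (default [transition_table()]).
#' @return A `state_machine` list with `state`, `active`, `table`.
#' @export
#' @examples
#' m <- fsm_new()
#' st <- fsm_step(m, "SMP3")
#' st$point
fsm_new <- function(table = transition_table()) {
  structure(
    list(state = "S1", active = TRUE, table = table),
    class = "state_machine"
  )
}

#' Reset the machine
#'
#' Explicit reactivation: returns the machine to S1, active. This is the only
#' way to leave HOME after a NIM deactivation.
#'
#' @param machine A `state_machine`.
#' @return The reset machine.
#' @export
fsm_reset <- function(machine) {
  machine$state <- "S1"
  machine$active <- TRUE
  machine
}

state_point <- function(state) {
  if (state == "HOME") {
    return(c(px = NA_real_, py = NA_real_, pz = NA_real_))
  }
  tt <- state_targets()
  r <- tt[tt$state == state, ]
  c(px = r$px, py = r$py, pz = r$pz)
}

#' Advance the machine by one event
#'
#' @param machine A `state_machine`.
#' @param event A class name (`"SMP"`, `"SMP3"`, `"SMP5"`, `"NIM"`), a 4-bit
#'   word as produced by [encode_inputs()] (`"0000"` meaning no event leaves
#'   the machine unchanged), or `"reset"`.
#' @return A list with the updated `machine`, the emitted `point` (named
#'   `px`, `py`, `pz`; `NA` at HOME) and the resulting `state`.
#' @export
fsm_step <- function(machine, event) {
  if (!inherits(machine, "state_machine")) {
    rlang::abort("`machine` must come from fsm_new().")
  }
  if (identical(event, "reset")) {
    machine <- fsm_reset(machine)
    return(list(
      machine = machine, state = machine$state,
      point = state_point(machine$state)
    ))
  }
  cls <- decode_event(event)
  if (is.null(cls)) { # zero word: no event
    return(list(
      machine = machine, state = machine$state,
      point = state_point(machine$state)
    ))
  }
  if (!machine$active) {
    rlang::warn("Machine is deactivated; event ignored (reset required).")
    return(list(
      machine = machine, state = machine$state,
      point = state_point(machine$state)
    ))
  }
  if (cls == "NIM") {
    machine$state <- "HOME"
    machine$active <- FALSE
  } else {
    machine$state <- machine$table[[machine$state]][[cls]]
  }
  list(
    machine = machine, state = machine$state,
    point = state_point(machine$state)
  )
}

decode_event <- function(event) {
  if (event %in% contraction_classes()$class) {
    return(event)
  }
  if (grepl("^[01]{4}$", event)) {
    if (event == "0000") {
      return(NULL)
    }
    m <- c(`1000` = "NIM", `0100` = "SMP3", `0010` = "SMP5", `0001` = "SMP")
    if (!event %in% names(m)) {
      rlang::abort("Input word must be one-hot (or 0000).")
    }
    return(m[[event]])
  }
  rlang::abort(paste0("Unknown event: ", event))
}

#' Run a sequence of events through the machine
#'
#' Folds [fsm_step()] over the events starting from a fresh (or supplied)
#' machine and returns the visited states and emitted set-points.
#'
#' @param events Character vector of class names / words.
#' @param machine Optional starting machine (default [fsm_new()]).
#' @return A tibble with one row per event: `event`, `state`, `active`,
#'   `px`, `py`, `pz`. The final machine is attached as attribute `machine`.
#' @export
#' @examples
#' run_sequence(c("SMP3", "SMP5"))
run_sequence <- function(events, machine = fsm_new()) {
  rows <- vector("list", length(events))
  for (i in seq_along(events)) {
    st <- fsm_step(machine, events[i])
    machine <- st$machine
    rows[[i]] <- tibble::tibble(
      event = events[i], state = st$state, active = machine$active,
      px = st$point[["px"]], py = st$point[["py"]], pz = st$point[["pz"]]
    )
  }
  out <- dplyr::bind_rows(rows)
  if (length(events) == 0) {
    out <- tibble::tibble(
      event = character(0), state = character(0), active = logical(0),
      px = numeric(0), py = numeric(0), pz = numeric(0)
    )
  }
  attr(out, "machine") <- machine
  out
}
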