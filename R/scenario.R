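# Driving scene geometry. The car travels along +x at (nominally constant)
# speed; y is lateral, positive to the driver's right. Pedestrians appear
# ahead at a signed eccentricity and walk perpendicular to the road on a
# constant-bearing collision course, stopping at the lane edge.

MPH_TO_MPS <- 0.44704
M_TO_FT <- 1 / 0.3048

#' Scenario configuration
#'
#' Parameters of one drive type. City drives run at 30 mph with pedestrians
#' appearing 220 ft (67 m) ahead; highway drives at 60 mph with appearances
#' at 440 ft (134 m). Appearance distance is the distance the car covers in
#' `appearance_travel_time` (5 s) — twice the conventional 2.5 s
#' perception-brake sight distance. Appearances are evenly divided among the
#' four eccentricities (±4°, ±14° relative to car heading).
#'
#' @param drive_type `"city"` or `"highway"`.
#' @param car_speed Car speed, m/s. Defaults: city 13.41 (30 mph), highway
#'   26.82 (60 mph).
#' @param appearance_travel_time Seconds of car travel to the appearance
#'   point; also the pedestrian's nominal time to reach the lane edge.
#' @param eccentricities Signed pedestrian appearance eccentricities, degrees.
#' @param n_appearances Total pedestrian appearances; must divide evenly
#'   among the eccentricities.
#' @param pedestrian_height Pedestrian height, m.
#' @param deceleration Braking deceleration used for the stopping-distance
#'   criterion, m/s² (5 m/s²: dry level road, good tires).
#' @param eye_height Driver eye height above the road, m.
#' @param lane_half_width Distance from car path to lane edge, m.
#' @param sim_rate Simulator output rate, Hz.
#' @return A list of class `scenario_config`.
#' @examples
#' cfg <- scenario_config("city")
#' appearance_distance(cfg$car_speed, cfg$appearance_travel_time)
#' @export
scenario_config <- function(drive_type = c("city", "highway"),
                            car_speed = NULL,
                            appearance_travel_time = 5,
                            eccentricities = c(-14, -4, 4, 14),
                            n_appearances = 104L,
                            pedestrian_height = 2,
                            deceleration = 5,
                            eye_height = 1.2,
                            lane_half_width = 1.8,
                            sim_rate = 30) {
  drive_type <- match.arg(drive_type)
  if (is.null(car_speed)) {
    car_speed <- if (drive_type == "city") 30 * MPH_TO_MPS else 60 * MPH_TO_MPS
  }
  if (!is.finite(car_speed) || car_speed <= 0) abort("car_speed must be > 0")
  if (deceleration <= 0) abort("deceleration must be > 0")
  if (appearance_travel_time <= 0) abort("appearance_travel_time must be > 0")
  if (any(eccentricities == 0)) abort("eccentricities must be non-zero")
  n_appearances <- as.integer(n_appearances)
  if (n_appearances %% length(eccentricities) != 0L) {
    abort("n_appearances must divide evenly among the eccentricities")
  }
  structure(
    list(
      drive_type = drive_type,
      car_speed = car_speed,
      appearance_travel_time = appearance_travel_time,
      eccentricities = eccentricities,
      n_appearances = n_appearances,
      pedestrian_height = pedestrian_height,
      deceleration = deceleration,
      eye_height = eye_height,
      lane_half_width = lane_half_width,
      sim_rate = sim_rate
    ),
    class = "scenario_config"
  )
}

#' Pedestrian appearance distance
#'
#' Distance ahead of the car at which a pedestrian appears: the distance the
#' car covers in the appearance travel time at its current speed
#' (220 ft at 30 mph over 5 s; 440 ft at 60 mph).
#'
#' @param speed Car speed, m/s (> 0).
#' @param travel_time Seconds (> 0).
#' @return A tibble with the distance in `meters` and `feet`.
#' @export
appearance_distance <- function(speed, travel_time = 5) {
  if (any(!is.finite(speed)) || any(speed <= 0)) abort("speed must be > 0")
  if (any(!is.finite(travel_time)) || any(travel_time <= 0)) abort("travel_time must be > 0")
  m <- speed * travel_time
  tibble::tibble(meters = m, feet = m * M_TO_FT)
}

#' Vehicle stopping distance
#'
#' Distance needed to brake to a stop from the given speed at constant
#' deceleration: speed² / (2 × deceleration). Braking is assumed to begin at
#' the horn-press instant.
#'
#' @param speed Speed at the press, m/s (>= 0).
#' @param deceleration m/s² (> 0).
#' @return Metres.
#' @export
stopping_distance <- function(speed, deceleration = 5) {
  if (any(!is.finite(speed)) || any(speed < 0)) abort("speed must be >= 0")
  if (any(!is.finite(deceleration)) || any(deceleration <= 0)) abort("deceleration must be > 0")
  speed^2 / (2 * deceleration)
}

#' Define a pedestrian appearance event
#'
#' @param event_id Label.
#' @param eccentricity Signed appearance eccentricity, degrees (non-zero;
#'   the sign is the side of the road).
#' @param t_appear Appearance time, s.
#' @param cfg A [scenario_config()].
#' @return A one-row tibble describing the event: appearance distance,
#'   lateral speed (constant-bearing formula, car_speed × tan|eccentricity|),
#'   and the event window.
#' @export
pedestrian_event <- function(event_id, eccentricity, t_appear, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (eccentricity == 0) abort("eccentricity 0 has no collision-course geometry")
  d <- cfg$car_speed * cfg$appearance_travel_time
  tibble::tibble(
    event_id = as.character(event_id),
    eccentricity = eccentricity,
    t_appear = t_appear,
    appearance_distance = d,
    lateral_speed = cfg$car_speed * tan(abs(eccentricity) * pi / 180),
    window = cfg$appearance_travel_time
  )
}

#' Collision-course pedestrian trajectory
#'
#' Positions the pedestrian at the appearance distance ahead of the car at a
#' lateral offset chosen so its bearing equals the nominal eccentricity, then
#' moves it perpendicular to the road at constant lateral speed
#' `car_speed × tan(|eccentricity|)` toward the travel lane. While both car
#' and pedestrian move at constant speed the bearing is exactly constant
#' (collision course); the pedestrian stops at the lane edge and never enters
#' the lane.
#'
#' @param cfg A [scenario_config()].
#' @param ev A one-row event from [pedestrian_event()].
#' @param car_x0 Car along-track position at the event's appearance time, m.
#' @return A tibble at the simulator rate: `t`, `ped_x` (along-track
#'   station, constant), `ped_y` (lateral, signed), `moving`.
#' @export
make_trajectory <- function(cfg, ev, car_x0 = 0) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (ev$eccentricity == 0) abort("eccentricity 0 has no collision-course geometry")
  dt <- 1 / cfg$sim_rate
  tt <- seq(0, ev$window, by = dt)
  d <- ev$appearance_distance
  side <- sign(ev$eccentricity)
  y0 <- d * tan(abs(ev$eccentricity) * pi / 180)
  y <- pmax(y0 - ev$lateral_speed * tt, cfg$lane_half_width)
  tibble::tibble(
    t = ev$t_appear + tt,
    ped_x = car_x0 + d,
    ped_y = side * y,
    moving = y > cfg$lane_half_width
  )
}

#' Project a pedestrian into head-centred visual angles
#'
#' The pedestrian is modelled as a vertical line segment: azimuth is the
#' signed bearing relative to car heading, and the elevation span runs from
#' the foot (ground level) to the head, both measured from the driver's eye
#' height by arctangent at the current range.
#'
#' @param car_x,car_y Car position, m (vectors allowed).
#' @param ped_x,ped_y Pedestrian position, m.
#' @param cfg A [scenario_config()].
#' @return A tibble with `azimuth`, `elevation_bottom`, `elevation_top`
#'   (degrees); rows with non-positive range (pedestrian passed) are `NA`.
#' @export
project_to_angles <- function(car_x, ped_x, ped_y, cfg, car_y = 0) {
  stopifnot(inherits(cfg, "scenario_config"))
  rng <- ped_x - car_x
  ok <- rng > 0
  az <- ifelse(ok, atan((ped_y - car_y) / rng) * 180 / pi, NA_real_)
  bot <- ifelse(ok, atan((0 - cfg$eye_height) / rng) * 180 / pi, NA_real_)
  top <- ifelse(ok, atan((cfg$pedestrian_height - cfg$eye_height) / rng) * 180 / pi, NA_real_)
  tibble::tibble(azimuth = az, elevation_bottom = bot, elevation_top = top)
}

#' Classify a horn press as timely or untimely
#'
#' A reaction is timely if, at the press, braking at the configured
#' deceleration would stop the car before the pedestrian's projected crossing
#' point (its along-road station), i.e. the remaining distance to the station
#' is at least the stopping distance at the instantaneous speed. The
#' collision is counterfactual — pedestrians never actually enter the lane —
#' and the boundary case (remaining distance exactly equal to the stopping
#' distance) counts as timely.
#'
#' @param remaining_distance Distance from the car at the press to the
#'   pedestrian's station, m.
#' @param speed_at_press Car speed at the press, m/s.
#' @param deceleration m/s².
#' @return Logical: `TRUE` for timely.
#' @examples
#' is_timely(134, 26.82)  # press at appearance on a highway: timely
#' is_timely(50, 26.82)   # 50 m remaining at 60 mph: untimely
#' @export
is_timely <- function(remaining_distance, speed_at_press, deceleration = 5) {
  remaining_distance >= stopping_distance(speed_at_press, deceleration)
}
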