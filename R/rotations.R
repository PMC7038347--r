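# Small rotation utilities shared by the synthetic generator and the
# strapdown wrappers. Rotation matrices map sensor/body frame -> navigation
# frame (ENU, z up); gravity acts as (0, 0, -g) on the carrier, so a level
# stationary accelerometer reads +g on its up axis.

rot_x <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3)
}

rot_y <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}

rot_z <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

# gravity leveling: roll/pitch from the mean specific force while static,
# yaw fixed to 0 (shape, not absolute heading, is reconstructed)
attitude_from_accel <- function(f_mean) {
  roll <- atan2(f_mean[2], f_mean[3])
  pitch <- atan2(-f_mean[1], sqrt(f_mean[2]^2 + f_mean[3]^2))
  rot_y(pitch) %*% rot_x(roll)
}

wrap_angle <- function(a) atan2(sin(a), cos(a))
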