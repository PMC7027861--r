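# MicrobeJ delimited export preset (documented dialect; native session
# files are not parsed). 1-based coordinates.
preset = microbej
base = 1
cell_id = NAME
spot_id = NAME
object_id = NAME
frame_id = POSITION
vertex = INDEX
x = LOCATION.x
y = LOCATION.y
intensity = INTENSITY
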