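[radar]
fc = 60000000000
B = 3890000000
T = 0.00005
M = 50
frame_rate = 20
n_samples = 256
n_tx = 2
n_rx = 4

[motion]
f_br = 0.25
a_br = 0.002
f_hr = 1.25
a_hr = 0.0003

[scene]
sigma = 1
noise_std = 0
taper_k = 1.3
seed = 1

[point.1]
distance = 0.9
angle = -40

[point.2]
distance = 0.9
angle = -20

[point.3]
distance = 0.9
angle = 0

[point.4]
distance = 0.9
angle = 20

[point.5]
distance = 0.9
angle = 40

[point.6]
distance = 1.2
angle = -40

[point.7]
distance = 1.2
angle = -20

[point.8]
distance = 1.2
angle = 0

[point.9]
distance = 1.2
angle = 20

[point.10]
distance = 1.2
angle = 40

[point.11]
distance = 1.5
angle = -40

[point.12]
distance = 1.5
angle = -20

[point.13]
distance = 1.5
angle = 0

[point.14]
distance = 1.5
angle = 20

[point.15]
distance = 1.5
angle = 40

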