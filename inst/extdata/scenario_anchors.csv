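# Synthetic active-travel scenario anchors (weekly km per inhabitant; e-bike
# share as a fraction of cycled km). Cycling and e-bike-share anchors mirror
# the printed transition-scenario values; the walking level in 2021 is a
# synthetic choice (its +11% rise over 2021-2050 is the scenario's).
series,year,value
cycling,2021,2.4
cycling,2040,17.1
cycling,2045,17.5
cycling,2050,17.1
walking,2021,3.4
walking,2050,3.774
ebike_share,2021,0.033
ebike_share,2040,0.70
ebike_share,2050,0.70
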