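# Paper-like fixture: single resident, five days, eight sensors.
# Breakfast between 8 and 10, shower ~15 min later, dinner 18:40-20:30.
DAYS
5

# Sensors repeat within activities (fridge opened several times while
# cooking, and so on): interval counts of 2-5 are typical of real
# dense-sensing logs.
ACTIVITIES
PrepareBreakfast 2
0.6 cupCupboardSens@0 fridgeSens@30 fridgeSens@60 plateCupboardSens@45 microwaveSens@30 fridgeSens@120 microwaveSens@90
0.4 plateCupboardSens@0 panCupboardSens@20 fridgeSens@40 fridgeSens@30 microwaveSens@60 cupCupboardSens@45
TakeShower 1
1.0 hallToiletDoorSens@0 hallToiletDoorSens@600
PrepareDinner 2
0.5 freezerSens@0 freezerSens@45 panCupboardSens@60 microwaveSens@300 fridgeSens@60 plateCupboardSens@120 plateCupboardSens@30
0.5 groceryCupboardSens@0 panCupboardSens@45 fridgeSens@30 fridgeSens@90 groceryCupboardSens@60 plateCupboardSens@240 microwaveSens@60

BEHAVIOURS
Prob 1.0
S 8:00 - 10:00 PrepareBreakfast@0 TakeShower@900
S 18:40 - 20:30 PrepareDinner@0

NOISE
fridgeSens 0.04
hallToiletDoorSens 0.02
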