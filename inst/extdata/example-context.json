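{
  "objects": [
    {"name": "panCupboard", "location": "kitchen", "attached_sensor": "panCupboardSens"},
    {"name": "plateCupboard", "location": "kitchen", "attached_sensor": "plateCupboardSens"},
    {"name": "cupCupboard", "location": "kitchen", "attached_sensor": "cupCupboardSens"},
    {"name": "fridge", "location": "kitchen", "attached_sensor": "fridgeSens"},
    {"name": "microwave", "location": "kitchen", "attached_sensor": "microwaveSens"},
    {"name": "hallToiletDoor", "location": "hall", "attached_sensor": "hallToiletDoorSens"},
    {"name": "freezer", "location": "kitchen", "attached_sensor": "freezerSens"},
    {"name": "groceryCupboard", "location": "kitchen", "attached_sensor": "groceryCupboardSens"}
  ],
  "sensors": [
    {"name": "panCupboardSens", "type": "contact"},
    {"name": "plateCupboardSens", "type": "contact"},
    {"name": "cupCupboardSens", "type": "contact"},
    {"name": "fridgeSens", "type": "contact"},
    {"name": "microwaveSens", "type": "contact"},
    {"name": "hallToiletDoorSens", "type": "contact"},
    {"name": "freezerSens", "type": "contact"},
    {"name": "groceryCupboardSens", "type": "contact"}
  ],
  "error_models": {"contact": 0.0208}
}
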