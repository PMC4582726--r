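# Default ruleset: 15 safe (Datalog) rules over the embryo ontology.
# Syntax: ID: pattern & pattern ... => pattern & ... ; variables start with ?.

# lineage between embryological entities
R1:  ?x mcfe:directly_develops_from ?y => ?x mcfe:develops_from ?y
R2:  ?x mcfe:develops_from ?y & ?y mcfe:develops_from ?z => ?x mcfe:develops_from ?z
R3:  ?x mcfe:directly_develops_from ?y & ?y mcfe:part_of ?z => ?x mcfe:develops_from ?z
R4:  ?x mcfe:directly_develops_from ?y & ?y rdfs:subClassOf ?z => ?x mcfe:develops_from ?z

# generic RDFS / mereology core
R5:  ?x rdfs:subClassOf ?y & ?y rdfs:subClassOf ?z => ?x rdfs:subClassOf ?z
R6:  ?x mcfe:part_of ?y & ?y mcfe:part_of ?z => ?x mcfe:part_of ?z
R7:  ?p rdfs:subPropertyOf ?q & ?x ?p ?y => ?x ?q ?y

# geometric representations of organ instances
R8:  ?i rdf:type ?e & ?s mcfe:describes ?i & ?s mcfe:has_geometrical_representation ?g => ?g mcfe:represents ?i
R9:  ?g mcfe:represents ?i & ?s mcfe:has_geometrical_representation ?g & ?s mcfe:at_stage ?t => ?g mcfe:represents ?i & ?g mcfe:geometry_at_stage ?t

# temporal order and process dependencies
R10: ?x mcfe:following_stage ?y & ?y mcfe:following_stage ?z => ?x mcfe:following_stage ?z
R11: ?p mcfe:depends_on ?q & ?q mcfe:depends_on ?r => ?p mcfe:depends_on ?r
R12: ?d mcfe:impacts_processus ?p & ?p mcfe:depends_on ?q => ?d mcfe:impacts_processus ?q
R13: ?s mcfe:has_process ?p & ?s mcfe:describes ?i => ?p mcfe:impacts_entity ?i
R14: ?s mcfe:has_process ?p & ?s mcfe:from_stage ?t => ?p mcfe:process_from_stage ?t
R15: ?s mcfe:has_process ?p & ?s mcfe:to_stage ?t => ?p mcfe:process_to_stage ?t
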