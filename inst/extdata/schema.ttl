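@prefix mcfe: <http://example.org/mycf-embryo#> .
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .

mcfe:embryological_entity a rdfs:Class .
mcfe:temporal_entity a rdfs:Class .
mcfe:geometrical_entity a rdfs:Class .
mcfe:process a rdfs:Class .
mcfe:spatio_temporal_representation a rdfs:Class .
mcfe:disease a rdfs:Class .
mcfe:point rdfs:subClassOf mcfe:geometrical_entity .
mcfe:line rdfs:subClassOf mcfe:geometrical_entity .
mcfe:plane rdfs:subClassOf mcfe:geometrical_entity .
mcfe:ovoid rdfs:subClassOf mcfe:geometrical_entity .
mcfe:cylinder rdfs:subClassOf mcfe:geometrical_entity .
mcfe:duct rdfs:subClassOf mcfe:geometrical_entity .
mcfe:growth rdfs:subClassOf mcfe:process .
mcfe:migration rdfs:subClassOf mcfe:process .
mcfe:rotation rdfs:subClassOf mcfe:process .
mcfe:interaction rdfs:subClassOf mcfe:process .
mcfe:division rdfs:subClassOf mcfe:process .
mcfe:fixation rdfs:subClassOf mcfe:process .
mcfe:directly_develops_from rdfs:subPropertyOf mcfe:develops_from .
mcfe:migration_direction rdfs:subPropertyOf mcfe:vector_coordinates .
mcfe:x_axis_orientation rdfs:subPropertyOf mcfe:vector_coordinates .
mcfe:y_axis_orientation rdfs:subPropertyOf mcfe:vector_coordinates .
mcfe:z_axis_orientation rdfs:subPropertyOf mcfe:vector_coordinates .
mcfe:caudal_end_axis_size rdfs:subPropertyOf mcfe:axis_size .
mcfe:rostral_end_axis_size rdfs:subPropertyOf mcfe:axis_size .
mcfe:caudal_end_barycenter_position rdfs:subPropertyOf mcfe:barycenter_position .
mcfe:rostral_end_barycenter_position rdfs:subPropertyOf mcfe:barycenter_position .
mcfe:caudal_end_vector_coordinates rdfs:subPropertyOf mcfe:vector_coordinates .
mcfe:rostral_end_vector_coordinates rdfs:subPropertyOf mcfe:vector_coordinates .
mcfe:rostral_end_growth_proportion rdfs:subPropertyOf mcfe:growth_proportion .
mcfe:caudal_end_growth_proportion rdfs:subPropertyOf mcfe:growth_proportion .
mcfe:rostral_end_fixed_to rdfs:subPropertyOf mcfe:fixed_to .
mcfe:caudal_end_fixed_to rdfs:subPropertyOf mcfe:fixed_to .
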