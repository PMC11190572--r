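# Namespace IRI bases shared across the package.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"
SH_NS   <- "http://www.w3.org/ns/shacl#"
PHS_NS  <- "https://w3id.org/phenoscribe/"
OBO_NS  <- "http://purl.obolibrary.org/obo/"
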